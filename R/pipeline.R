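#' Pipeline configuration with study-default thresholds
#'
#' Every default is a threshold of the analysed study design: gene
#' expressed at FPKM > 0.1, isoform at FPKM > 0.01, differential splicing
#' at FDR < 0.05 and |ΔPSI| > 0.1, major isoform at usage ratio > 0.5,
#' switch cutoff 0.3, lincRNA distance 2 kb, long 3' UTR > 580 nt,
#' stop-to-junction distance > 50 nt, lncRNA ORF filter 100 aa.
#'
#' @param ... named overrides of the defaults.
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    gene_fpkm = 0.1, iso_fpkm = 0.01,
    delta_psi = 0.1, fdr = 0.05,
    major_ratio = 0.5, switch_cutoff = 0.3,
    linc_distance = 2000L,
    utr3_threshold = 580L, eej_distance = 50L,
    orf_aa = 100L,
    k_psi = 10L, k_det = 12L,
    de_alpha = 0.05,
    n_random_control = 1000L,
    seed = 1L
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  stopifnot(all(vapply(cfg[c("gene_fpkm", "iso_fpkm", "delta_psi", "fdr",
                             "major_ratio", "switch_cutoff", "linc_distance",
                             "utr3_threshold", "eej_distance", "orf_aa")],
                       function(x) x > 0, logical(1))))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full isoform-level analysis pipeline
#'
#' Stages: load annotation and expression -> locus grouping -> AS event
#' enumeration -> PSI / differential splicing -> differential expression
#' (stand-in caller) -> DE/DS sets and correlations -> major-isoform
#' switches -> lncRNA classification and partner correlation -> NMD
#' screen -> summary JSON.  Deterministic given inputs and config seed;
#' every summary number is recomputable from the stage TSVs written to
#' `outdir`.
#'
#' @param gtf annotation path (GTF or GFF3).
#' @param expression expression TSV path ([read_expression_tsv()] format).
#' @param outdir output directory for stage reports.
#' @param junctions optional junction-support BED path.
#' @param labels optional coding-potential label TSV.
#' @param config a [pipeline_config()].
#' @return the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(gtf, expression, outdir,
                         junctions = NULL, labels = NULL,
                         config = pipeline_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, fun) {
    tryCatch(fun, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tx <- stage("load", read_gtf(gtf))
  expr <- stage("load", read_expression_tsv(expression))

  loci <- stage("loci", group_into_loci(tx))
  tx <- assign_loci(tx, loci)
  iso_hist <- isoforms_per_locus_histogram(loci)
  exon_stats <- exons_per_isoform_stats(tx)

  coding_tx <- tx[tx$biotype != "lncRNA", , drop = FALSE]
  events <- stage("events", enumerate_all_events(coding_tx))
  if (nrow(events)) write_events_tsv(events, file.path(outdir, "events.tsv"))

  junction_support <- NA_real_
  if (!is.null(junctions)) {
    support <- read_junction_bed(junctions)
    junction_support <- junction_support_fraction(all_junctions(tx), support)
  }

  calls <- stage("diff_splicing", diff_splicing_calls(
    events, expr, fdr_threshold = config$fdr,
    delta_psi_threshold = config$delta_psi))
  utils::write.table(calls[, c("event_id", "time_point", "delta_psi",
                               "p_value", "fdr", "significant")],
                     file.path(outdir, "ds_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dpsi <- delta_psi_matrix(calls[calls$event_id %in%
                                   calls$event_id[calls$significant], ,
                                 drop = FALSE])
  psi_clusters <- if (nrow(dpsi) >= config$k_psi) {
    cluster_delta_psi(dpsi, config$k_psi)
  } else NULL
  stages_ds <- ds_gene_stages(calls, events)

  gene_expr <- stage("expression", gene_expression_from_isoforms(expr, tx))
  expressed <- apply_expression_thresholds(gene_expr, expr,
                                           gene_fpkm = config$gene_fpkm,
                                           iso_fpkm = config$iso_fpkm)
  de_genes <- stage("de", call_de_any_time(gene_expr, alpha = config$de_alpha))
  ds_genes <- sort(unique(c(stages_ds$early, stages_ds$late)))
  sets <- build_de_ds_sets(de_genes, ds_genes, expressed$expressed_genes,
                           n_random = config$n_random_control,
                           seed = config$seed)
  de_counts <- vapply(unique(expr$design$time), function(tp) {
    de <- call_de(gene_expr, tp, alpha = config$de_alpha)
    sum(de$significant)
  }, numeric(1))
  ds_counts <- stages_ds$ds_genes_by_time$n_ds_genes
  dsg_deg <- if (stats::sd(ds_counts) > 0 && stats::sd(de_counts) > 0) {
    dsg_deg_count_correlation(ds_counts, de_counts)
  } else list(r = NA_real_, p_value = NA_real_)
  scc <- gene_transcript_scc(sets$de_no_ds, gene_expr, expr, tx)

  mcalls <- stage("switches", call_major_isoforms(expr, tx,
                                                  iso_fpkm = config$iso_fpkm))
  switches <- detect_switches(mcalls, min_ratio_change = config$switch_cutoff)
  switches <- categorize_switches(switches, expr$design)
  if (nrow(switches)) {
    utils::write.table(
      data.frame(locus_id = switches$locus_id, former = switches$former,
                 latter = switches$latter,
                 ratio_change = switches$ratio_change,
                 category = switches$category,
                 times = vapply(switches$switch_times, paste,
                                character(1), collapse = ",")),
      file.path(outdir, "switches.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  lnc_summary <- list(n_candidates = 0L, n_antisense = 0L, n_intergenic = 0L,
                      median_rho_antisense = NA_real_,
                      median_rho_intergenic = NA_real_)
  if (!is.null(labels)) {
    lab <- tibble::as_tibble(utils::read.delim(labels,
                                               stringsAsFactors = FALSE))
    cand <- filter_lnc_candidates(tx, lab, max_orf_aa = config$orf_aa)
    lnc_tx <- tx[tx$transcript_id %in% cand, , drop = FALSE]
    pc_tx <- tx[tx$biotype == "coding", , drop = FALSE]
    if (nrow(lnc_tx)) {
      cls <- classify_all_lnc(lnc_tx, pc_tx,
                              linc_distance = config$linc_distance)
      utils::write.table(cls, file.path(outdir, "lncrna_classes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      corr <- lnc_pc_correlation(cls, expr)
      lnc_summary <- list(
        n_candidates = nrow(cls),
        n_antisense = sum(cls$category == "antisense"),
        n_intergenic = sum(cls$category == "intergenic"),
        median_rho_antisense =
          unname(corr$category_medians["antisense"]) %||% NA_real_,
        median_rho_intergenic =
          unname(corr$category_medians["intergenic"]) %||% NA_real_
      )
    }
  }

  nmd <- stage("nmd", screen_nmd_all(tx, utr3_threshold = config$utr3_threshold,
                                     eej_distance = config$eej_distance))
  if (nrow(nmd)) {
    utils::write.table(nmd, file.path(outdir, "nmd_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_transcripts = nrow(tx),
    n_loci = nrow(loci),
    multi_isoform_fraction = attr(iso_hist, "multi_isoform_fraction"),
    mean_exons_per_isoform = exon_stats$mean,
    n_as_events = nrow(events),
    events_by_type = as.list(table(events$event_type)),
    junction_support_fraction = junction_support,
    n_ds_events = length(unique(calls$event_id[calls$significant])),
    n_ds_genes = length(ds_genes),
    n_de_genes = length(de_genes),
    n_de_no_ds = length(sets$de_no_ds),
    n_no_de_ds = length(sets$no_de_ds),
    n_de_ds = length(sets$de_ds),
    dsg_deg_r = dsg_deg$r,
    median_scc_de_no_ds = scc$median_rho,
    n_switch_loci = length(unique(switches$locus_id)),
    switches_by_category = as.list(table(switches$category)),
    lncrna = lnc_summary,
    n_nmd_candidates = sum(nmd$nmd_candidate),
    nmd_candidate_fraction = if (nrow(nmd)) mean(nmd$nmd_candidate) else NA_real_,
    n_psi_clusters = if (is.null(psi_clusters)) 0L else
      length(unique(psi_clusters)),
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
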