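#' Configuration for the synthetic transcriptome generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: multi-isoform loci whose extra isoforms differ from a base
#' isoform by one structured splicing edit, planted major-isoform switches
#' with specified timing and condition pattern, planted differential
#' splicing with a specified ΔPSI, antisense/intergenic lncRNAs with a
#' target expression correlation to their partner locus, planted
#' NMD-feature isoforms, and multiplicative log-normal replicate noise.
#' The source study provides no generative model; every distributional
#' choice here is a documented stand-in (see the methods vignette).
#'
#' @param n_loci number of protein-coding loci.
#' @param isoforms_per_locus_probs probabilities for 1..K isoforms per
#'   locus (sum to 1); default puts ~65% of loci in the multi-isoform
#'   classes, most of them with 2-6 isoforms.
#' @param exons_per_isoform_mean target mean exon count of base isoforms.
#' @param exon_length_range,intron_length_range uniform sampling ranges
#'   (nt); introns must be long enough to host interior edits.
#' @param design an [experimental_design()].
#' @param n_planted_switches number of planted major-isoform switches.
#' @param switch_categories category pattern recycled over the planted
#'   switches (`stage_specific`, `continuous`, `irreversible_inoculated`).
#' @param switch_timing time point of stage-specific switches (must be in
#'   the design).
#' @param n_planted_ds_events planted differential-splicing events.
#' @param ds_timing time point at which the planted ΔPSI applies.
#' @param delta_psi_planted signed PSI difference (inoculated minus
#'   uninoculated) at the planted time, in (0, 1].
#' @param n_lncnat,n_lincrna planted antisense / intergenic lncRNAs.
#' @param lnc_pc_correlation target Spearman rho between lncNATs and their
#'   partner locus (lincRNA pairs are generated independent, rho 0).
#' @param n_planted_nmd coding isoforms engineered with an NMD feature
#'   (alternating long-3'UTR and stop-to-junction types).
#' @param noise_sd_log2 replicate noise sd on the log2 scale.
#' @param seed integer seed; fully determines all outputs.
#' @return validated config list of class `simulation_config`.
#' @export
simulation_config <- function(n_loci = 50L,
                              isoforms_per_locus_probs =
                                c(0.35, 0.25, 0.15, 0.10, 0.06, 0.04, 0.03, 0.02),
                              exons_per_isoform_mean = 8,
                              exon_length_range = c(80L, 300L),
                              intron_length_range = c(100L, 400L),
                              design = experimental_design(),
                              n_planted_switches = 0L,
                              switch_categories = c("stage_specific",
                                                    "continuous",
                                                    "irreversible_inoculated"),
                              switch_timing = 15,
                              n_planted_ds_events = 0L,
                              ds_timing = 15,
                              delta_psi_planted = 0.4,
                              n_lncnat = 0L, n_lincrna = 0L,
                              lnc_pc_correlation = 0.9,
                              n_planted_nmd = 0L,
                              noise_sd_log2 = 0.25,
                              seed = 1L) {
  cfg <- list(
    n_loci = as.integer(n_loci),
    isoforms_per_locus_probs = isoforms_per_locus_probs /
      sum(isoforms_per_locus_probs),
    exons_per_isoform_mean = exons_per_isoform_mean,
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    design = design,
    n_planted_switches = as.integer(n_planted_switches),
    switch_categories = switch_categories,
    switch_timing = switch_timing,
    n_planted_ds_events = as.integer(n_planted_ds_events),
    ds_timing = ds_timing,
    delta_psi_planted = delta_psi_planted,
    n_lncnat = as.integer(n_lncnat),
    n_lincrna = as.integer(n_lincrna),
    lnc_pc_correlation = lnc_pc_correlation,
    n_planted_nmd = as.integer(n_planted_nmd),
    noise_sd_log2 = noise_sd_log2,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_loci >= 0L, cfg$n_planted_switches >= 0L,
    cfg$n_planted_ds_events >= 0L, cfg$n_lncnat >= 0L, cfg$n_lincrna >= 0L,
    cfg$n_planted_nmd >= 0L, cfg$noise_sd_log2 >= 0,
    cfg$delta_psi_planted > 0, cfg$delta_psi_planted <= 1,
    abs(cfg$lnc_pc_correlation) <= 1,
    all(cfg$switch_categories %in% c("stage_specific", "continuous",
                                     "irreversible_inoculated")),
    all(cfg$switch_timing %in% design$time)
  )
  if (cfg$exon_length_range[1] < 20L || cfg$intron_length_range[1] < 60L) {
    stop("infeasible geometry: exons must be >= 20 nt and introns >= 60 nt ",
         "to host interior splice-site edits")
  }
  n_planted_loci <- cfg$n_planted_switches + cfg$n_planted_ds_events +
    cfg$n_lncnat
  if (n_planted_loci > cfg$n_loci) {
    stop("not enough loci to host all planted switches, DS events and ",
         "lncNAT partners (need ", n_planted_loci, ", have ", cfg$n_loci, ")")
  }
  class(cfg) <- "simulation_config"
  cfg
}

# one structured splicing edit on a base exon chain ---------------------------
# returns list(exons, type, var_start, var_end, inclusion_role) where
# inclusion_role says whether the "base" or the "variant" chain is the
# inclusion isoform of the resulting event
apply_splice_edit <- function(ex, type, strand) {
  ex <- matrix(as.integer(ex), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
  uv <- function(x) as.integer(unname(x))
  n <- nrow(ex)
  pick <- function(v) if (length(v) == 1L) v else sample(v, 1L)
  if (n < 2L) return(NULL)
  if (type %in% c("ES", "MXE") && n < 3L) return(NULL)
  if (type == "IR") {
    k <- pick(seq_len(n - 1L))
    vs <- ex[k, 2]; ve <- ex[k + 1L, 1]
    merged <- rbind(
      ex[seq_len(k - 1L), , drop = FALSE],
      c(ex[k, 1], ex[k + 1L, 2]),
      if (k + 2L <= n) ex[(k + 2L):n, , drop = FALSE]
    )
    return(list(exons = merged, type = "IR", var_start = uv(vs),
                var_end = uv(ve), inclusion_role = "variant"))
  }
  if (type == "ES") {
    k <- pick(2:(n - 1L))
    return(list(exons = ex[-k, , drop = FALSE], type = "ES",
                var_start = uv(ex[k, 1]), var_end = uv(ex[k, 2]),
                inclusion_role = "base"))
  }
  if (type %in% c("A5SS", "A3SS")) {
    k <- pick(seq_len(n - 1L))
    exon_left_len <- ex[k, 2] - ex[k, 1]
    exon_right_len <- ex[k + 1L, 2] - ex[k + 1L, 1]
    intron_len <- ex[k + 1L, 1] - ex[k, 2]
    # which genomic boundary moves: donor is the intron's 5' side
    move_left <- (type == "A5SS") == (strand == "+")
    dmax <- min(25L, intron_len - 10L,
                if (move_left) exon_left_len - 10L else exon_right_len - 10L)
    if (dmax < 6L) return(NULL)
    d <- pick(6:dmax)
    v <- ex
    if (move_left) {
      v[k, 2] <- v[k, 2] - d
      vs <- v[k, 2]; ve <- ex[k, 2]
    } else {
      v[k + 1L, 1] <- v[k + 1L, 1] + d
      vs <- ex[k + 1L, 1]; ve <- v[k + 1L, 1]
    }
    return(list(exons = v, type = type, var_start = uv(vs),
                var_end = uv(ve), inclusion_role = "base"))
  }
  if (type == "MXE") {
    # replace an internal exon with a novel exon inside the downstream intron
    cands <- 2:(n - 1L)
    gaps <- ex[cands + 1L, 1] - ex[cands, 2]
    ok <- which(gaps >= 40L)
    if (!length(ok)) return(NULL)
    k <- cands[pick(ok)]
    gap <- ex[k + 1L, 1] - ex[k, 2]
    len <- min(40L, gap - 12L)
    ns <- ex[k, 2] + (gap - len) %/% 2L
    v <- ex
    v[k, ] <- c(ns, ns + len)
    return(list(exons = v, type = "MXE",
                var_start = uv(ex[k, 1]), var_end = uv(ns + len),
                inclusion_role = if (strand == "+") "base" else "variant"))
  }
  stop("unknown edit type ", type)
}

#' Generate a single-edit transcript pair
#'
#' Builds a random base exon chain and a variant differing by exactly one
#' splicing edit of the requested type; used for oracle testing of the
#' event classifier.
#'
#' @param type one of IR, ES, A5SS, A3SS, MXE.
#' @param n_exons exon count of the base chain (>= 5 recommended).
#' @param strand `"+"` or `"-"`.
#' @param chrom chromosome name.
#' @param exon_length_range,intron_length_range sampling ranges.
#' @return list with `pair` (two-row `transcript_models`), `truth`
#'   (type/var region/inclusion id).
#' @export
simulate_edit_pair <- function(type, n_exons = 6L, strand = "+",
                               chrom = "chr1",
                               exon_length_range = c(80L, 300L),
                               intron_length_range = c(100L, 400L)) {
  repeat {
    ex <- random_exon_chain(n_exons, exon_length_range, intron_length_range,
                            start = 1000L)
    ed <- apply_splice_edit(ex, type, strand)
    if (!is.null(ed)) break
  }
  pair <- transcript_models(
    transcript_id = c("base.1", "variant.1"),
    locus_id = "L1", chrom = chrom, strand = strand,
    exons = list(ex, ed$exons), biotype = "coding"
  )
  inc <- if (ed$inclusion_role == "base") "base.1" else "variant.1"
  list(pair = pair,
       truth = tibble::tibble(
         event_type = ed$type, var_start = ed$var_start,
         var_end = ed$var_end, inclusion_id = inc,
         exclusion_id = setdiff(c("base.1", "variant.1"), inc)
       ))
}

random_exon_chain <- function(n_exons, exon_length_range, intron_length_range,
                              start) {
  el <- sample(exon_length_range[1]:exon_length_range[2], n_exons,
               replace = TRUE)
  il <- if (n_exons > 1L) {
    sample(intron_length_range[1]:intron_length_range[2], n_exons - 1L,
           replace = TRUE)
  } else integer(0)
  s <- start + c(0L, cumsum(el[-n_exons] + il))
  cbind(start = s, end = s + el)
}

#' Generate a synthetic annotation with planted ground truth
#'
#' See [simulation_config()] for what is planted.  Loci are placed
#' non-overlapping on one chromosome with >= 5 kb gaps; each
#' multi-isoform locus derives its extra isoforms from the base isoform by
#' one structured splicing edit each (recorded in the truth set); planted
#' lncNATs overlap their partner locus antisense, planted lincRNAs sit
#' > 2 kb from every coding locus; planted NMD isoforms carry an
#' engineered 3' UTR > 580 nt or a junction > 50 nt downstream of the stop.
#'
#' @param config a [simulation_config()].
#' @return list with `transcripts` (a `transcript_models` tibble) and
#'   `truth` (see [write_truth_json()]).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  K <- length(config$isoforms_per_locus_probs)
  n <- config$n_loci
  # role assignment: disjoint locus sets for switches, DS events, lncNAT
  # partners (planted correlation profiles must not disturb other planting)
  roles <- rep("free", n)
  idx <- seq_len(n)
  take <- function(k, role) {
    free <- which(roles == "free")
    sel <- free[seq_len(k)]
    roles[sel] <<- role
    sel
  }
  sw_loci <- take(config$n_planted_switches, "switch")
  ds_loci <- take(config$n_planted_ds_events, "ds")
  nat_loci <- take(config$n_lncnat, "lncnat")

  n_iso <- sample.int(K, n, replace = TRUE,
                      prob = config$isoforms_per_locus_probs)
  n_iso[sw_loci] <- pmax(n_iso[sw_loci], 2L)
  # DS loci get exactly two isoforms so the planted pair fully defines the
  # event's inclusion/exclusion sets (no sibling isoforms diluting PSI)
  n_iso[ds_loci] <- 2L

  cursor <- 10000L
  tx_rows <- list()
  gap_starts <- integer(0); gap_ends <- integer(0)
  planted_events <- list()
  edit_types <- c("IR", "ES", "A5SS", "A3SS", "MXE")

  for (li in seq_len(n)) {
    locus_id <- sprintf("PB.%d", li)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- if (n_iso[li] > 1L || config$n_planted_nmd > 0L) {
      max(5L, stats::rpois(1L, config$exons_per_isoform_mean - 1) + 1L)
    } else {
      max(1L, stats::rpois(1L, config$exons_per_isoform_mean - 1) + 1L)
    }
    base <- random_exon_chain(n_ex, config$exon_length_range,
                              config$intron_length_range, start = cursor)
    exons <- list(base)
    ids <- sprintf("%s.%d", locus_id, 1L)
    if (n_iso[li] > 1L) {
      for (vi in 2:n_iso[li]) {
        ed <- NULL
        for (attempt in seq_len(20L)) {
          ed <- apply_splice_edit(base, sample(edit_types, 1L), strand)
          if (!is.null(ed)) break
        }
        if (is.null(ed)) ed <- apply_splice_edit(base, "ES", strand)
        vid <- sprintf("%s.%d", locus_id, vi)
        exons[[vi]] <- ed$exons
        ids <- c(ids, vid)
        inc <- if (ed$inclusion_role == "base") ids[1L] else vid
        planted_events[[length(planted_events) + 1L]] <- tibble::tibble(
          locus_id = locus_id, event_type = ed$type,
          var_start = ed$var_start, var_end = ed$var_end,
          inclusion_id = inc,
          exclusion_id = setdiff(c(ids[1L], vid), inc)
        )
      }
    }
    span_end <- max(vapply(exons, function(e) e[nrow(e), 2], integer(1)))
    tx_rows[[li]] <- tibble::tibble(
      transcript_id = ids, locus_id = locus_id, chrom = "chr1",
      strand = strand, biotype = "coding",
      exons = exons
    )
    gap <- sample(6000:9000, 1L)
    gap_starts <- c(gap_starts, span_end)
    gap_ends <- c(gap_ends, span_end + gap)
    cursor <- span_end + gap
  }
  tx <- dplyr::bind_rows(tx_rows)
  tx$cds_start <- NA_integer_; tx$cds_end <- NA_integer_
  class(tx) <- c("transcript_models", class(tx))
  pe <- dplyr::bind_rows(c(list(tibble::tibble(
    locus_id = character(0), event_type = character(0),
    var_start = integer(0), var_end = integer(0),
    inclusion_id = character(0), exclusion_id = character(0))),
    planted_events))

  # planted switches: former = isoform 1, latter = isoform 2
  late_times <- intersect(c(15, 20, 25), config$design$time)
  sw <- if (length(sw_loci)) {
    cats <- rep_len(config$switch_categories, length(sw_loci))
    t0 <- vapply(seq_along(sw_loci), function(i) {
      if (cats[i] == "stage_specific") {
        as.numeric(sample(rep(config$switch_timing, 2L), 1L))
      } else {
        as.numeric(sample(rep(late_times, 2L), 1L))
      }
    }, numeric(1))
    tibble::tibble(
      locus_id = sprintf("PB.%d", sw_loci),
      former = sprintf("PB.%d.1", sw_loci),
      latter = sprintf("PB.%d.2", sw_loci),
      category = cats, t0 = t0
    )
  } else {
    tibble::tibble(locus_id = character(0), former = character(0),
                   latter = character(0), category = character(0),
                   t0 = numeric(0))
  }

  # planted DS events: the first edit event of each designated locus
  ds <- if (length(ds_loci)) {
    sel <- pe[match(sprintf("PB.%d", ds_loci), pe$locus_id), , drop = FALSE]
    tibble::tibble(
      locus_id = sel$locus_id, event_type = sel$event_type,
      var_start = sel$var_start, var_end = sel$var_end,
      inclusion_id = sel$inclusion_id, exclusion_id = sel$exclusion_id,
      time = rep_len(config$ds_timing, nrow(sel)),
      delta_psi = config$delta_psi_planted
    )
  } else {
    tibble::tibble(locus_id = character(0), event_type = character(0),
                   var_start = integer(0), var_end = integer(0),
                   inclusion_id = character(0), exclusion_id = character(0),
                   time = numeric(0), delta_psi = numeric(0))
  }

  # planted lncNATs: single-exon antisense transcript over the partner
  # locus' base isoform first exons
  lnc_rows <- list()
  lnc_pairs <- list()
  for (i in seq_along(nat_loci)) {
    li <- nat_loci[i]
    partner <- sprintf("PB.%d.1", li)
    pex <- tx$exons[[match(partner, tx$transcript_id)]]
    lnc_id <- sprintf("LNCNAT.%d", i)
    s <- pex[1, 1] + 5L
    e <- min(pex[min(2L, nrow(pex)), 2] - 5L, s + 1500L)
    anti <- if (tx$strand[match(partner, tx$transcript_id)] == "+") "-" else "+"
    lnc_rows[[length(lnc_rows) + 1L]] <- tibble::tibble(
      transcript_id = lnc_id, locus_id = lnc_id, chrom = "chr1",
      strand = anti, biotype = "lncRNA",
      cds_start = NA_integer_, cds_end = NA_integer_,
      exons = list(cbind(start = s, end = e))
    )
    lnc_pairs[[length(lnc_pairs) + 1L]] <- tibble::tibble(
      lnc_id = lnc_id, partner_id = partner,
      partner_locus = sprintf("PB.%d", li),
      target_rho = config$lnc_pc_correlation,
      category = "antisense", subcategory = "lncNAT_exonic"
    )
  }
  # planted lincRNAs: centred in inter-locus gaps, > 2 kb from neighbours.
  # Both flanking loci must be free of planted structure (a partner locus
  # receives the pair's latent profile and must not carry other planting).
  linc_gaps <- integer(0)
  for (g in seq_len(n)) {
    if (length(linc_gaps) >= config$n_lincrna) break
    if (gap_ends[g] - gap_starts[g] < 6000L) next
    if (roles[g] != "free") next
    if (g < n && roles[g + 1L] != "free") next
    linc_gaps <- c(linc_gaps, g)
    roles[g] <- "lincflank"
    if (g < n) roles[g + 1L] <- "lincflank"
  }
  if (length(linc_gaps) < config$n_lincrna) {
    stop("infeasible geometry: not enough free inter-locus gaps for ",
         config$n_lincrna, " lincRNAs")
  }
  for (i in seq_along(linc_gaps)) {
    g <- linc_gaps[i]
    mid <- (gap_starts[g] + gap_ends[g]) %/% 2L
    len <- sample(400:1200, 1L)
    s <- mid - len %/% 2L
    lnc_id <- sprintf("LINC.%d", i)
    # nearest PC transcript: the locus upstream of this gap (distance
    # measured between span boundaries)
    d_up <- s - gap_starts[g]
    d_down <- gap_ends[g] - (s + len)
    partner_locus <- if (d_up <= d_down) sprintf("PB.%d", g) else
      sprintf("PB.%d", min(g + 1L, config$n_loci))
    lnc_rows[[length(lnc_rows) + 1L]] <- tibble::tibble(
      transcript_id = lnc_id, locus_id = lnc_id, chrom = "chr1",
      strand = sample(c("+", "-"), 1L), biotype = "lncRNA",
      cds_start = NA_integer_, cds_end = NA_integer_,
      exons = list(cbind(start = s, end = s + len))
    )
    lnc_pairs[[length(lnc_pairs) + 1L]] <- tibble::tibble(
      lnc_id = lnc_id, partner_id = sprintf("%s.1", partner_locus),
      partner_locus = partner_locus,
      target_rho = 0,
      category = "intergenic", subcategory = "lincRNA_distal"
    )
  }
  if (length(lnc_rows)) {
    tx <- dplyr::bind_rows(tx, dplyr::bind_rows(lnc_rows))
    class(tx) <- c("transcript_models", class(tx))
  }
  pairs <- dplyr::bind_rows(c(list(tibble::tibble(
    lnc_id = character(0), partner_id = character(0),
    partner_locus = character(0), target_rho = numeric(0),
    category = character(0), subcategory = character(0))),
    lnc_pairs))
  tx$exons <- lapply(tx$exons, as_exon_matrix)

  # CDS assignment for coding transcripts + planted NMD features
  coding_idx <- which(tx$biotype == "coding")
  nmd_pool <- coding_idx[vapply(tx$exons[coding_idx], nrow, integer(1)) >= 3L]
  nmd_pool <- setdiff(nmd_pool, match(ds$inclusion_id, tx$transcript_id))
  n_nmd <- min(config$n_planted_nmd, length(nmd_pool))
  nmd_idx <- if (n_nmd) nmd_pool[seq_len(n_nmd)] else integer(0)
  nmd_feature <- character(0)
  for (ii in seq_along(coding_idx)) {
    i <- coding_idx[ii]
    one <- tx[i, , drop = FALSE]
    total <- sum(one$exons[[1L]][, 2] - one$exons[[1L]][, 1])
    j <- transcript_junction_offsets(one)
    if (i %in% nmd_idx) {
      want_long <- (match(i, nmd_idx) %% 2L) == 1L
      if (want_long && total >= 700L) {
        utr3 <- 600L
        feature <- "long_utr3"
      } else if (length(j)) {
        utr3 <- total - (max(j) - 60L)   # stop 60 nt upstream of last EEJ
        feature <- "ptc_junction"
      } else {
        utr3 <- 600L; feature <- "long_utr3"
      }
      nmd_feature <- c(nmd_feature, feature)
    } else {
      # stop inside the last exon, 3' UTR <= 400 nt: a clean NMD negative
      last_len <- total - (if (length(j)) max(j) else 0L)
      utr3 <- min(400L, max(10L, last_len - 10L))
    }
    utr5 <- min(60L, max(3L, total %/% 20L))
    cds_len <- total - utr5 - utr3
    cds_len <- cds_len - (cds_len %% 3L)
    if (cds_len < 30L) { # shrink UTRs for very short transcripts
      utr5 <- 3L; utr3 <- max(3L, total - 3L - 33L)
      cds_len <- total - utr5 - utr3
      cds_len <- cds_len - (cds_len %% 3L)
    }
    orf_start <- utr5; orf_end <- utr5 + cds_len
    g1 <- map_from_transcript_coords(one, orf_start)
    g2 <- map_from_transcript_coords(one, orf_end - 1L)
    tx$cds_start[i] <- min(g1, g2)
    tx$cds_end[i] <- max(g1, g2) + 1L
  }
  validate_transcripts(tx)

  truth <- list(
    planted_as_events = pe,
    planted_switches = sw,
    planted_ds_events = ds,
    planted_lnc_pairs = pairs,
    planted_nmd_isoforms = tibble::tibble(
      transcript_id = tx$transcript_id[nmd_idx],
      feature = nmd_feature
    )
  )
  validate_truth(truth, tx)
  list(transcripts = tx, truth = truth)
}

validate_truth <- function(truth, tx) {
  ids <- tx$transcript_id
  ref <- c(truth$planted_switches$former, truth$planted_switches$latter,
           truth$planted_ds_events$inclusion_id,
           truth$planted_ds_events$exclusion_id,
           truth$planted_lnc_pairs$lnc_id,
           truth$planted_lnc_pairs$partner_id,
           truth$planted_nmd_isoforms$transcript_id)
  if (!all(ref %in% ids)) {
    stop("truth set references unknown transcripts: ",
         paste(utils::head(setdiff(ref, ids), 5), collapse = ", "))
  }
  invisible(truth)
}

#' Generate an expression matrix honouring the planted truth
#'
#' Baseline per-isoform abundances are log-normal (log2 FPKM ~ N(3, 1.5))
#' and constant over the design grid except where the truth set plants
#' structure: switch loci exchange major-isoform proportions between the
#' former and latter isoform across the prescribed cells; DS events fix
#' the inclusion/exclusion abundance ratio to the planted PSI per
#' condition; lnc/partner pairs share a latent temporal profile whose
#' noise is calibrated so the target Spearman rho holds in expectation.
#' Replicate noise is multiplicative log-normal with sd `noise_sd_log2`
#' on the log2 scale.
#'
#' @param transcripts,truth output of [generate_annotation()].
#' @param config the same [simulation_config()].
#' @return an [expression_matrix()] over the configured design.
#' @export
generate_expression <- function(transcripts, truth, config) {
  validate_truth(truth, transcripts)
  set.seed(config$seed + 1000003L)
  d <- config$design
  ids <- transcripts$transcript_id
  nfeat <- length(ids)
  cells <- unique(d[, c("condition", "time")])
  ncell <- nrow(cells)
  conds <- attr(d, "conditions")
  inoc <- conds[1L]

  base_log2 <- stats::rnorm(nfeat, mean = 3, sd = 1.5)
  cellv <- matrix(2^base_log2, nrow = nfeat, ncol = ncell,
                  dimnames = list(ids, paste(cells$condition, cells$time,
                                             sep = "_")))

  # planted switches: former/latter proportions within the locus
  sw <- truth$planted_switches
  for (i in seq_len(nrow(sw))) {
    members <- which(transcripts$locus_id == sw$locus_id[i])
    total <- sum(2^base_log2[members])
    fi <- match(sw$former[i], ids); la <- match(sw$latter[i], ids)
    others <- setdiff(members, c(fi, la))
    p_other <- if (length(others)) 0.1 else 0
    share <- if (length(others)) p_other * total / length(others) else 0
    pre <- c(0.7, 0.2) * (1 - p_other) / 0.9 * total   # former, latter
    swapped_cell <- switch(
      sw$category[i],
      stage_specific = cells$condition == inoc & cells$time == sw$t0[i],
      continuous = cells$condition != inoc & cells$time >= sw$t0[i],
      irreversible_inoculated = cells$condition == inoc &
        cells$time >= sw$t0[i]
    )
    for (ci in seq_len(ncell)) {
      if (swapped_cell[ci]) {
        cellv[fi, ci] <- pre[2L]; cellv[la, ci] <- pre[1L]
      } else {
        cellv[fi, ci] <- pre[1L]; cellv[la, ci] <- pre[2L]
      }
      if (length(others)) cellv[others, ci] <- share
    }
  }

  # planted DS events: PSI = 0.3 baseline, +delta in inoculated at the
  # planted time
  ds <- truth$planted_ds_events
  for (i in seq_len(nrow(ds))) {
    inc <- match(ds$inclusion_id[i], ids); exc <- match(ds$exclusion_id[i], ids)
    tot <- 2^base_log2[inc] + 2^base_log2[exc]
    p0 <- 0.3
    for (ci in seq_len(ncell)) {
      psi <- p0 + if (cells$condition[ci] == inoc &&
                      cells$time[ci] %in% ds$time[i]) ds$delta_psi[i] else 0
      cellv[inc, ci] <- psi * tot
      cellv[exc, ci] <- (1 - psi) * tot
    }
  }

  # planted lnc / partner-locus correlation via a shared latent profile
  pairs <- truth$planted_lnc_pairs
  times <- unique(cells$time)
  for (i in seq_len(nrow(pairs))) {
    z_shared <- stats::rnorm(length(times))
    z_lnc <- stats::rnorm(length(times))
    rho_s <- pairs$target_rho[i]
    lnc_i <- match(pairs$lnc_id[i], ids)
    partner_members <- which(transcripts$locus_id == pairs$partner_locus[i])
    if (abs(rho_s) < 1e-12) {
      prof_lnc <- z_lnc
      prof_pc <- z_shared
      sd_extra <- 0
    } else {
      rho_p <- 2 * sin(pi * rho_s / 6)      # Spearman -> Pearson (normal)
      v <- 1 / abs(rho_p) - 1
      sd_extra <- sqrt(max(0, v - config$noise_sd_log2^2))
      prof_lnc <- sign(rho_p) * z_shared
      prof_pc <- z_shared
    }
    tmatch <- match(cells$time, times)
    cellv[lnc_i, ] <- 2^(base_log2[lnc_i] + prof_lnc[tmatch] +
                           stats::rnorm(ncell, sd = sd_extra))
    for (m in partner_members) {
      cellv[m, ] <- cellv[m, ] * 2^(prof_pc[tmatch] +
                                      stats::rnorm(ncell, sd = sd_extra))
    }
  }

  # expand to replicates with multiplicative log-normal noise
  cell_of_sample <- match(paste(d$condition, d$time, sep = "_"),
                          colnames(cellv))
  vals <- cellv[, cell_of_sample, drop = FALSE]
  colnames(vals) <- d$sample_id
  if (config$noise_sd_log2 > 0) {
    vals <- vals * 2^matrix(stats::rnorm(length(vals),
                                         sd = config$noise_sd_log2),
                            nrow = nfeat)
  }
  expression_matrix(vals, d)
}

#' Junction support set with uniform dropout
#'
#' Returns the union of all transcript junctions with each junction kept
#' independently with probability `1 - dropout_fraction`, emulating a
#' short-read junction set that misses a fraction of true junctions.
#'
#' @param transcripts `transcript_models` tibble.
#' @param dropout_fraction in \[0, 1\].
#' @param seed RNG seed.
#' @return junction tibble (chrom, strand, intron_start, intron_end).
#' @export
generate_junction_support_set <- function(transcripts, dropout_fraction,
                                          seed = 1L) {
  stopifnot(dropout_fraction >= 0, dropout_fraction <= 1)
  j <- all_junctions(transcripts)
  if (!nrow(j)) return(j)
  set.seed(seed)
  keep <- stats::runif(nrow(j)) >= dropout_fraction
  j[keep, , drop = FALSE]
}

#' Coding-potential labels for a generated annotation
#'
#' Emulates an externally supplied coding-potential classification: coding
#' biotypes are labelled `coding`, lncRNA biotypes `noncoding`, with the
#' ORF length (aa) derived from the annotated CDS (0 for transcripts
#' without one).
#'
#' @param transcripts `transcript_models` tibble.
#' @return tibble (transcript_id, label, orf_aa).
#' @export
generate_coding_labels <- function(transcripts) {
  cl <- cds_lengths(transcripts)
  tibble::tibble(
    transcript_id = transcripts$transcript_id,
    label = ifelse(transcripts$biotype == "lncRNA", "noncoding", "coding"),
    orf_aa = ifelse(is.na(cl), 0L, pmax(0L, cl %/% 3L - 1L))
  )
}

#' Write / read the truth set as JSON
#' @param truth truth list from [generate_annotation()].
#' @param path JSON path.
#' @return `path` invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(lapply(truth, as.data.frame), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, tibble::as_tibble)
}

#' Simulate a complete dataset to disk
#'
#' Writes annotation (GTF + GFF3), expression TSV, junction-support BED,
#' coding-potential labels TSV and the truth-set JSON into `outdir`.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @param junction_dropout dropout fraction for the support set.
#' @return invisible list of written paths plus the in-memory objects.
#' @export
simulate_dataset <- function(config, outdir, junction_dropout = 0.1784) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  expr <- generate_expression(ann$transcripts, ann$truth, config)
  support <- generate_junction_support_set(ann$transcripts, junction_dropout,
                                           seed = config$seed + 7L)
  paths <- list(
    gtf = file.path(outdir, "models.gtf"),
    gff3 = file.path(outdir, "models.gff3"),
    expression = file.path(outdir, "expression.tsv"),
    junctions = file.path(outdir, "junction_support.bed"),
    labels = file.path(outdir, "coding_labels.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_gtf(ann$transcripts, paths$gtf, format = "gtf")
  write_gtf(ann$transcripts, paths$gff3, format = "gff3")
  write_expression_tsv(expr, paths$expression)
  write_junction_bed(support, paths$junctions)
  utils::write.table(generate_coding_labels(ann$transcripts), paths$labels,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth_json(ann$truth, paths$truth)
  invisible(c(paths, list(transcripts = ann$transcripts, truth = ann$truth,
                          expression_data = expr)))
}
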