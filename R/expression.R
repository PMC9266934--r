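#' Experimental design for a two-condition time course
#'
#' @param conditions ordered condition labels; the first is treated as the
#'   treatment (inoculated) arm in condition contrasts.
#' @param time_points ordered numeric time labels (days post-inoculation).
#' @param replicates replicates per (condition, time) cell.
#' @return tibble (sample_id, condition, time, replicate) with unique
#'   sample ids `<condition>_<time>_<rep>`.
#' @export
experimental_design <- function(conditions = c("inoculated", "uninoculated"),
                                time_points = c(1, 4, 6, 8, 10, 15, 20, 25, 30),
                                replicates = 3L) {
  stopifnot(length(conditions) >= 1L, length(time_points) >= 1L,
            replicates >= 1L, !anyDuplicated(conditions),
            !anyDuplicated(time_points))
  g <- expand.grid(replicate = seq_len(replicates), time = time_points,
                   condition = conditions, stringsAsFactors = FALSE)
  d <- tibble::tibble(
    sample_id = sprintf("%s_%g_%d", g$condition, g$time, g$replicate),
    condition = g$condition, time = g$time, replicate = g$replicate
  )
  stopifnot(!anyDuplicated(d$sample_id))
  attr(d, "conditions") <- conditions
  attr(d, "time_points") <- time_points
  d
}

#' Expression matrix container
#'
#' @param values numeric feature x sample matrix of FPKM (non-negative),
#'   with rownames = feature ids and colnames = design sample ids.
#' @param design tibble from [experimental_design()].
#' @return an `expression_matrix` object (list with `values`, `design`).
#' @export
expression_matrix <- function(values, design) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            setequal(colnames(values), design$sample_id),
            all(values >= 0))
  values <- values[, design$sample_id, drop = FALSE]
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%s conditions, %s time points)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$condition)),
              length(unique(x$design$time))))
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' Header is `transcript_id` followed by the sample ids.
#'
#' @param expr an `expression_matrix`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(transcript_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV into an `expression_matrix`
#'
#' Sample ids in the header must follow `<condition>_<time>_<rep>`; the
#' design is reconstructed from them unless supplied.
#'
#' @param path TSV path.
#' @param design optional design tibble; inferred from the header if NULL.
#' @return an `expression_matrix`.
#' @export
read_expression_tsv <- function(path, design = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  if (is.null(design)) {
    parts <- strsplit(colnames(vals), "_")
    design <- tibble::tibble(
      sample_id = colnames(vals),
      condition = vapply(parts, function(p) paste(p[seq_len(length(p) - 2L)],
                                                  collapse = "_"), character(1)),
      time = as.numeric(vapply(parts, function(p) p[length(p) - 1L], character(1))),
      replicate = as.integer(vapply(parts, function(p) p[length(p)], character(1)))
    )
  }
  expression_matrix(vals, design)
}

#' Replicate-mean expression per (condition, time) cell
#' @param expr an `expression_matrix`.
#' @return list with `values` (feature x cell matrix) and `cells` tibble
#'   (cell_id, condition, time).
#' @export
replicate_means <- function(expr) {
  d <- expr$design
  cell <- paste(d$condition, d$time, sep = "_")
  cells <- unique(tibble::tibble(cell_id = cell, condition = d$condition,
                                 time = d$time))
  m <- vapply(cells$cell_id, function(cid) {
    rowMeans(expr$values[, cell == cid, drop = FALSE])
  }, numeric(nrow(expr$values)))
  if (nrow(expr$values) == 1L) m <- matrix(m, nrow = 1,
                                           dimnames = list(rownames(expr$values),
                                                           cells$cell_id))
  list(values = m, cells = cells)
}

#' Gene-level expression as the sum of member-isoform expression
#'
#' @param iso_expr isoform `expression_matrix`.
#' @param tx `transcript_models` tibble assigning each isoform to a locus.
#' @return gene-level `expression_matrix` (rows = locus ids).  Column sums
#'   are conserved exactly.
#' @export
gene_expression_from_isoforms <- function(iso_expr, tx) {
  ids <- rownames(iso_expr$values)
  locus <- tx$locus_id[match(ids, tx$transcript_id)]
  if (anyNA(locus)) {
    stop("isoform(s) without locus assignment: ",
         paste(utils::head(ids[is.na(locus)], 5), collapse = ", "))
  }
  g <- rowsum(iso_expr$values, group = locus)
  expression_matrix(g, iso_expr$design)
}

#' Apply the study expression thresholds
#'
#' A feature counts as expressed iff its FPKM strictly exceeds the
#' threshold in at least one sample (genes: FPKM > 0.1; isoforms:
#' FPKM > 0.01).
#'
#' @param gene_expr,iso_expr gene- and isoform-level `expression_matrix`.
#' @param gene_fpkm,iso_fpkm thresholds.
#' @return list with `expressed_genes`, `expressed_isoforms` (character).
#' @export
apply_expression_thresholds <- function(gene_expr, iso_expr,
                                        gene_fpkm = 0.1, iso_fpkm = 0.01) {
  list(
    expressed_genes = rownames(gene_expr$values)[
      apply(gene_expr$values > gene_fpkm, 1L, any)],
    expressed_isoforms = rownames(iso_expr$values)[
      apply(iso_expr$values > iso_fpkm, 1L, any)]
  )
}

welch_bh <- function(x_mat, y_mat) {
  # row-wise Welch t-test x vs y; returns two-sided p-values
  p <- vapply(seq_len(nrow(x_mat)), function(i) {
    x <- x_mat[i, ]; y <- y_mat[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  p
}

#' Differential-expression call at one time point
#'
#' Stand-in caller: Welch's t-test on log2(FPKM + 1), inoculated (first
#' condition) versus uninoculated, Benjamini-Hochberg adjusted.  Counts
#' from this caller are not comparable to count-model tools; it is a
#' calibrated, deterministic stand-in.
#'
#' @param expr `expression_matrix` (gene or transcript level).
#' @param time_point time to test.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return tibble (feature_id, log2fc, p_value, padj, significant).
#' @export
call_de <- function(expr, time_point, alpha = 0.05) {
  d <- expr$design
  conds <- unique(d$condition)
  stopifnot(length(conds) == 2L)
  sel1 <- d$sample_id[d$condition == conds[1] & d$time == time_point]
  sel2 <- d$sample_id[d$condition == conds[2] & d$time == time_point]
  if (length(sel1) < 2L || length(sel2) < 2L) {
    stop("need >= 2 replicates per condition at time ", time_point)
  }
  x <- log2(expr$values[, sel1, drop = FALSE] + 1)
  y <- log2(expr$values[, sel2, drop = FALSE] + 1)
  p <- welch_bh(x, y)
  padj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    feature_id = rownames(expr$values),
    log2fc = rowMeans(x) - rowMeans(y),
    p_value = p, padj = padj,
    significant = padj < alpha
  )
}

#' Differentially expressed features across all time points
#' @param expr `expression_matrix`.
#' @param alpha BH-adjusted level.
#' @return character vector: features significant at >= 1 time point.
#' @export
call_de_any_time <- function(expr, alpha = 0.05) {
  hits <- lapply(unique(expr$design$time), function(tp) {
    de <- call_de(expr, tp, alpha)
    de$feature_id[de$significant]
  })
  sort(unique(unlist(hits)))
}

#' Build the DE/DS gene sets and a seeded random control
#'
#' @param de_genes,ds_genes character vectors of gene ids flagged
#'   differentially expressed / differentially spliced (union over time).
#' @param expressed_genes universe for the random control.
#' @param n_random control size (capped at the universe size).
#' @param seed RNG seed for the control draw.
#' @return list with `de_no_ds`, `no_de_ds`, `de_ds`, `random_control`.
#' @export
build_de_ds_sets <- function(de_genes, ds_genes, expressed_genes,
                             n_random = 1000L, seed = 1L) {
  de_no_ds <- setdiff(de_genes, ds_genes)
  no_de_ds <- setdiff(ds_genes, de_genes)
  de_ds <- intersect(de_genes, ds_genes)
  rng <- local({ set.seed(seed); sample(expressed_genes,
                                        min(n_random, length(expressed_genes))) })
  list(de_no_ds = sort(de_no_ds), no_de_ds = sort(no_de_ds),
       de_ds = sort(de_ds), random_control = sort(rng))
}

#' Gene-transcript Spearman correlations for a gene set
#'
#' One Spearman rho per (gene, member transcript) pair, computed across the
#' full sample axis (average ranks under ties).  Pairs with a constant gene
#' or transcript profile are excluded and counted.
#'
#' @param gene_set character vector of locus ids.
#' @param gene_expr,iso_expr gene/isoform `expression_matrix` sharing a
#'   design.
#' @param tx `transcript_models` mapping transcripts to loci.
#' @return list with `pairs` tibble (locus_id, transcript_id, rho),
#'   `median_rho`, `n_excluded_constant`.
#' @export
gene_transcript_scc <- function(gene_set, gene_expr, iso_expr, tx) {
  members <- tx[tx$locus_id %in% gene_set &
                  tx$transcript_id %in% rownames(iso_expr$values), ,
                drop = FALSE]
  excl <- 0L
  rows <- lapply(seq_len(nrow(members)), function(i) {
    g <- gene_expr$values[members$locus_id[i], ]
    t <- iso_expr$values[members$transcript_id[i], ]
    if (stats::sd(g) == 0 || stats::sd(t) == 0) {
      excl <<- excl + 1L
      return(NULL)
    }
    tibble::tibble(locus_id = members$locus_id[i],
                   transcript_id = members$transcript_id[i],
                   rho = stats::cor(g, t, method = "spearman"))
  })
  pairs <- dplyr::bind_rows(rows)
  list(pairs = pairs,
       median_rho = if (nrow(pairs)) stats::median(pairs$rho) else NA_real_,
       n_excluded_constant = excl)
}

#' Correlation between per-time DS and DE counts
#'
#' Pearson correlation of the number of differentially spliced versus
#' differentially expressed genes across time points, with the usual
#' two-sided t-transform p-value.
#'
#' @param ds_counts,de_counts equal-length numeric vectors (one entry per
#'   time point, n >= 3).
#' @return list with `r` and `p_value`.
#' @export
dsg_deg_count_correlation <- function(ds_counts, de_counts) {
  stopifnot(length(ds_counts) == length(de_counts), length(ds_counts) >= 3L)
  if (stats::sd(ds_counts) == 0 || stats::sd(de_counts) == 0) {
    stop("zero variance in counts: correlation undefined")
  }
  ct <- stats::cor.test(ds_counts, de_counts, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
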