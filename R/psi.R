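#' Percent spliced in (PSI) per sample for an AS event
#'
#' PSI = sum of inclusion-isoform FPKM / (inclusion + exclusion FPKM),
#' computed per sample from transcript abundances.  PSI is undefined
#' (`NA`) when inclusion + exclusion abundance is zero; undefined records
#' are excluded downstream.
#'
#' @param event single event row (from [enumerate_locus_events()]) with
#'   `inclusion`/`exclusion` id list columns and an `event_id`.
#' @param expr isoform `expression_matrix`.
#' @return tibble (event_id, sample_id, psi, inclusion_abundance,
#'   exclusion_abundance).
#' @export
compute_psi <- function(event, expr) {
  stopifnot(nrow(event) == 1L)
  inc_ids <- event$inclusion[[1L]]
  exc_ids <- event$exclusion[[1L]]
  missing <- setdiff(c(inc_ids, exc_ids), rownames(expr$values))
  if (length(missing)) {
    stop("event isoform(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  inc <- colSums(expr$values[inc_ids, , drop = FALSE])
  exc <- colSums(expr$values[exc_ids, , drop = FALSE])
  tot <- inc + exc
  tibble::tibble(
    event_id = event$event_id,
    sample_id = colnames(expr$values),
    psi = unname(ifelse(tot > 0, inc / tot, NA_real_)),
    inclusion_abundance = unname(inc),
    exclusion_abundance = unname(exc)
  )
}

#' PSI matrix (events x samples) for an event table
#' @param events event tibble.
#' @param expr isoform `expression_matrix`.
#' @return numeric matrix, rownames = event ids, `NA` where undefined.
#' @export
compute_psi_matrix <- function(events, expr) {
  m <- t(vapply(seq_len(nrow(events)), function(i) {
    compute_psi(events[i, , drop = FALSE], expr)$psi
  }, numeric(ncol(expr$values))))
  rownames(m) <- events$event_id
  colnames(m) <- colnames(expr$values)
  m
}

logit_shrunk <- function(p, eps = 0.01) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Differential-splicing test for one event at one time point
#'
#' ΔPSI = mean(inoculated) - mean(uninoculated) on raw PSI; the p-value is
#' a Welch t-test on logit-transformed PSI with boundary shrinkage to
#' \[0.01, 0.99\] — a deterministic, calibrated stand-in for read-level
#' splicing tests.  Events with fewer than two defined replicate PSI
#' values in either condition are marked untestable (`NA` p) and excluded
#' from FDR adjustment.
#'
#' @param event_id event identifier (row of `psi_matrix`).
#' @param psi_matrix events x samples PSI matrix.
#' @param design design tibble matching the matrix columns.
#' @param time_point time to test.
#' @return one-row tibble (event_id, time_point, delta_psi, p_value,
#'   testable).
#' @export
test_event <- function(event_id, psi_matrix, design, time_point) {
  conds <- unique(design$condition)
  stopifnot(length(conds) == 2L)
  psi <- psi_matrix[event_id, ]
  x <- psi[design$sample_id[design$condition == conds[1] &
                              design$time == time_point]]
  y <- psi[design$sample_id[design$condition == conds[2] &
                              design$time == time_point]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    return(tibble::tibble(event_id = event_id, time_point = time_point,
                          delta_psi = NA_real_, p_value = NA_real_,
                          testable = FALSE))
  }
  dpsi <- mean(x) - mean(y)
  lx <- logit_shrunk(x); ly <- logit_shrunk(y)
  p <- if (stats::sd(lx) == 0 && stats::sd(ly) == 0) {
    if (isTRUE(all.equal(mean(lx), mean(ly)))) 1 else 0
  } else {
    tryCatch(stats::t.test(lx, ly)$p.value, error = function(e) 1)
  }
  tibble::tibble(event_id = event_id, time_point = time_point,
                 delta_psi = dpsi, p_value = p, testable = TRUE)
}

#' Benjamini-Hochberg adjustment and the combined significance filter
#'
#' Adjusts p-values across all testable events within each time point and
#' flags significance per the combined filter FDR < `fdr_threshold` AND
#' |ΔPSI| > `delta_psi_threshold`.
#'
#' @param calls tibble of [test_event()] rows.
#' @param fdr_threshold,delta_psi_threshold filter thresholds (defaults
#'   0.05 and 0.1).
#' @return `calls` with `fdr` and `significant` columns.
#' @export
fdr_adjust <- function(calls, fdr_threshold = 0.05,
                       delta_psi_threshold = 0.1) {
  calls$fdr <- NA_real_
  for (tp in unique(calls$time_point)) {
    sel <- which(calls$time_point == tp & calls$testable)
    calls$fdr[sel] <- stats::p.adjust(calls$p_value[sel], method = "BH")
  }
  calls$significant <- !is.na(calls$fdr) & calls$fdr < fdr_threshold &
    abs(calls$delta_psi) > delta_psi_threshold
  calls
}

#' Differential-splicing calls for all events across all time points
#' @param events event tibble.
#' @param expr isoform `expression_matrix`.
#' @param ... thresholds passed to [fdr_adjust()].
#' @return adjusted call tibble.
#' @export
diff_splicing_calls <- function(events, expr, ...) {
  psi <- compute_psi_matrix(events, expr)
  d <- expr$design
  calls <- dplyr::bind_rows(lapply(unique(d$time), function(tp) {
    dplyr::bind_rows(lapply(rownames(psi), function(eid) {
      test_event(eid, psi, d, tp)
    }))
  }))
  fdr_adjust(calls, ...)
}

#' ΔPSI matrix (events x time points) from call records
#'
#' Missing or untestable ΔPSI is imputed as 0 (no evidence of change),
#' matching the "no differential splicing" semantics used for clustering.
#'
#' @param calls call tibble from [diff_splicing_calls()].
#' @return numeric matrix, rows = event ids, columns = time points.
#' @export
delta_psi_matrix <- function(calls) {
  tps <- sort(unique(calls$time_point))
  ids <- unique(calls$event_id)
  m <- matrix(0, nrow = length(ids), ncol = length(tps),
              dimnames = list(ids, as.character(tps)))
  ok <- calls$testable & !is.na(calls$delta_psi)
  m[cbind(match(calls$event_id[ok], ids),
          match(calls$time_point[ok], tps))] <- calls$delta_psi[ok]
  m
}

#' Cluster temporal ΔPSI profiles
#'
#' Hierarchical clustering with Euclidean distance and average linkage,
#' cut into `k` clusters.
#'
#' @param delta_psi events x time matrix (complete; impute missing as 0
#'   beforehand via [delta_psi_matrix()]).
#' @param k number of clusters (1 <= k <= nrow).
#' @return named integer vector of cluster labels.
#' @export
cluster_delta_psi <- function(delta_psi, k) {
  if (k > nrow(delta_psi)) {
    stop("k = ", k, " exceeds the number of events (", nrow(delta_psi), ")")
  }
  if (k == 1L) {
    return(stats::setNames(rep(1L, nrow(delta_psi)), rownames(delta_psi)))
  }
  hc <- stats::hclust(stats::dist(delta_psi, method = "euclidean"),
                      method = "average")
  stats::cutree(hc, k = k)
}

#' Differentially spliced genes split into early and late stages
#'
#' @param calls significant-flagged call tibble.
#' @param events event tibble (maps event ids to loci).
#' @param late_from first time point counted as late (default 15).
#' @return list with `early`, `late` (locus id vectors) and
#'   `ds_genes_by_time` tibble (time_point, n_ds_genes).
#' @export
ds_gene_stages <- function(calls, events, late_from = 15) {
  locus_of <- stats::setNames(events$locus_id, events$event_id)
  sig <- calls[calls$significant, , drop = FALSE]
  gene_by_time <- split(unname(locus_of[sig$event_id]), sig$time_point)
  tps <- sort(unique(calls$time_point))
  counts <- tibble::tibble(
    time_point = tps,
    n_ds_genes = vapply(as.character(tps), function(tp) {
      length(unique(gene_by_time[[tp]]))
    }, integer(1))
  )
  early_tps <- tps[tps < late_from]
  late_tps <- tps[tps >= late_from]
  list(
    early = sort(unique(unlist(gene_by_time[as.character(early_tps)]))),
    late = sort(unique(unlist(gene_by_time[as.character(late_tps)]))),
    ds_genes_by_time = counts
  )
}
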