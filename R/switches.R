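#' Major-isoform calls per (locus, condition, time) cell
#'
#' Usage ratios are computed on replicate-mean FPKM over the expressed
#' isoforms of each locus (FPKM > `iso_fpkm` in at least one sample; the
#' denominator set is constant across cells).  The top isoform is reported
#' for every cell; it is the major isoform only when its ratio strictly
#' exceeds 0.5.  Cells with zero locus total get `ratio = 0` and no major.
#'
#' @param iso_expr isoform `expression_matrix`.
#' @param tx `transcript_models` tibble assigning isoforms to loci.
#' @param iso_fpkm expressed-isoform threshold (default 0.01).
#' @return tibble (locus_id, condition, time, major_isoform, top_isoform,
#'   ratio, n_expressed_isoforms) with attributes `ratio_matrix`
#'   (isoform x cell usage ratios) and `cells`.
#' @export
call_major_isoforms <- function(iso_expr, tx, iso_fpkm = 0.01) {
  rm_ <- replicate_means(iso_expr)
  cells <- rm_$cells
  expressed <- rownames(iso_expr$values)[
    apply(iso_expr$values > iso_fpkm, 1L, any)]
  keep <- intersect(expressed, tx$transcript_id)
  m <- rm_$values[keep, , drop = FALSE]
  locus <- tx$locus_id[match(keep, tx$transcript_id)]

  ratio_mat <- matrix(0, nrow = length(keep), ncol = nrow(cells),
                      dimnames = list(keep, cells$cell_id))
  rows <- list()
  for (li in unique(locus)) {
    idx <- which(locus == li)
    sub <- m[idx, , drop = FALSE]
    tot <- colSums(sub)
    r <- sweep(sub, 2L, ifelse(tot > 0, tot, 1), "/")
    r[, tot == 0] <- 0
    ratio_mat[idx, ] <- r
    top_i <- apply(r, 2L, which.max)
    top_ratio <- r[cbind(top_i, seq_len(ncol(r)))]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      locus_id = li,
      condition = cells$condition,
      time = cells$time,
      top_isoform = rownames(sub)[top_i],
      ratio = unname(top_ratio),
      major_isoform = ifelse(top_ratio > 0.5, rownames(sub)[top_i],
                             NA_character_),
      n_expressed_isoforms = length(idx)
    )
  }
  calls <- dplyr::bind_rows(rows)
  attr(calls, "ratio_matrix") <- ratio_mat
  attr(calls, "cells") <- cells
  attr(calls, "conditions") <- unique(iso_expr$design$condition)
  calls
}

#' Detect major-isoform switches
#'
#' A locus switches when two design cells carry different (non-missing)
#' major isoforms.  The ratio change of a candidate cell pair is the
#' maximum over the two involved isoforms of the absolute change in their
#' usage ratio between the cells; candidates with ratio change <=
#' `min_ratio_change` are discarded.  Qualifying cell pairs are recorded
#' as switch points and aggregated per (locus, isoform pair); the former
#' isoform is the one major at the earliest involved cell (ties broken
#' towards the control condition, i.e. the condition listed last in the
#' design).
#'
#' @param calls output of [call_major_isoforms()].
#' @param min_ratio_change usage-ratio change cutoff (default 0.3,
#'   strictly-greater rule).
#' @param inter_condition_only only compare cells from different
#'   conditions (default FALSE: cross-time comparisons within a condition
#'   also count).
#' @return tibble (locus_id, former, latter, ratio_change, n_switch_points,
#'   switch_points list column of cell pairs) with the majors matrix
#'   attached as attribute `major_matrix`.
#' @export
detect_switches <- function(calls, min_ratio_change = 0.3,
                            inter_condition_only = FALSE) {
  ratio_mat <- attr(calls, "ratio_matrix")
  cells <- attr(calls, "cells")
  conds <- attr(calls, "conditions")
  control <- conds[length(conds)]
  calls$cell_id <- paste(calls$condition, calls$time, sep = "_")

  out <- list()
  for (li in unique(calls$locus_id)) {
    sub <- calls[calls$locus_id == li, , drop = FALSE]
    sub <- sub[!is.na(sub$major_isoform), , drop = FALSE]
    if (nrow(sub) < 2L) next
    pts <- list()
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in (i + 1L):nrow(sub)) {
        if (sub$major_isoform[i] == sub$major_isoform[j]) next
        if (inter_condition_only && sub$condition[i] == sub$condition[j]) next
        a <- sub$major_isoform[i]; b <- sub$major_isoform[j]
        c1 <- sub$cell_id[i]; c2 <- sub$cell_id[j]
        rc <- max(abs(ratio_mat[a, c1] - ratio_mat[a, c2]),
                  abs(ratio_mat[b, c1] - ratio_mat[b, c2]))
        if (rc <= min_ratio_change) next
        pts[[length(pts) + 1L]] <- tibble::tibble(
          isoform_a = a, cond_a = sub$condition[i], time_a = sub$time[i],
          isoform_b = b, cond_b = sub$condition[j], time_b = sub$time[j],
          ratio_change = rc
        )
      }
    }
    if (!length(pts)) next
    pts <- dplyr::bind_rows(pts)
    pair_key <- apply(cbind(pts$isoform_a, pts$isoform_b), 1L,
                      function(x) paste(sort(x), collapse = "|"))
    for (pk in unique(pair_key)) {
      pp <- pts[pair_key == pk, , drop = FALSE]
      iso_pair <- strsplit(pk, "|", fixed = TRUE)[[1L]]
      # earliest involved cell decides the former isoform
      cellrows <- rbind(
        data.frame(iso = pp$isoform_a, cond = pp$cond_a, time = pp$time_a),
        data.frame(iso = pp$isoform_b, cond = pp$cond_b, time = pp$time_b)
      )
      cellrows <- cellrows[order(cellrows$time, cellrows$cond != control), ]
      former <- cellrows$iso[1L]
      latter <- setdiff(iso_pair, former)[1L]
      out[[length(out) + 1L]] <- tibble::tibble(
        locus_id = li, former = former, latter = latter,
        ratio_change = max(pp$ratio_change),
        n_switch_points = nrow(pp),
        switch_points = list(pp)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(locus_id = character(0), former = character(0),
                          latter = character(0), ratio_change = numeric(0),
                          n_switch_points = integer(0), switch_points = list())
  }
  # majors matrix: locus x cell of major isoforms, for categorization
  mm <- NULL
  if (nrow(calls)) {
    mm <- matrix(NA_character_, nrow = length(unique(calls$locus_id)),
                 ncol = nrow(cells),
                 dimnames = list(unique(calls$locus_id), cells$cell_id))
    mm[cbind(match(calls$locus_id, rownames(mm)),
             match(calls$cell_id, colnames(mm)))] <- calls$major_isoform
  }
  attr(res, "major_matrix") <- mm
  attr(res, "cells") <- cells
  attr(res, "conditions") <- conds
  res
}

#' Categorise isoform switches
#'
#' Uses the inter-condition, same-time switch points of each record: let T
#' be the set of times where the two conditions carry the two different
#' majors.
#' \itemize{
#'  \item `continuous`: T runs without interruption from some start t0 in
#'    `continuous_starts` through the final time point.  Additionally
#'    `irreversible_inoculated` when the inoculated arm (first condition)
#'    switches former -> latter at t0 and keeps the latter for the rest of
#'    the course while the uninoculated arm keeps the former throughout.
#'  \item `stage_specific`: T is a single time point.  Switches recurring
#'    at scattered, non-contiguous times are reported as one
#'    `stage_specific` record per time.
#' }
#' Records without any inter-condition same-time point (purely cross-time
#' switches) are categorised `stage_specific` at the earliest switch time.
#'
#' @param switches output of [detect_switches()].
#' @param design the experimental design.
#' @param continuous_starts admissible onset times for continuous switches
#'   (default the 15/20/25 dpi late stages present in the design).
#' @return switch tibble with `category` and `switch_times` columns
#'   (scattered stage-specific records exploded to one row per time).
#' @export
categorize_switches <- function(switches, design,
                                continuous_starts = c(15, 20, 25)) {
  mm <- attr(switches, "major_matrix")
  conds <- attr(switches, "conditions")
  inoc <- conds[1L]; ctrl <- conds[length(conds)]
  tps <- sort(unique(design$time))
  continuous_starts <- intersect(continuous_starts, tps)
  out <- list()
  for (i in seq_len(nrow(switches))) {
    rec <- switches[i, , drop = FALSE]
    pp <- rec$switch_points[[1L]]
    same_time <- pp[pp$time_a == pp$time_b & pp$cond_a != pp$cond_b, ,
                    drop = FALSE]
    T_ <- sort(unique(same_time$time_a))
    if (length(T_) == 0L) {
      rec$category <- "stage_specific"
      rec$switch_times <- list(min(c(pp$time_a, pp$time_b)))
      out[[length(out) + 1L]] <- rec
      next
    }
    contin_t0 <- NA_real_
    for (t0 in continuous_starts) {
      if (setequal(T_, tps[tps >= t0])) { contin_t0 <- t0; break }
    }
    if (!is.na(contin_t0)) {
      f <- rec$former; l <- rec$latter
      inoc_cells <- paste(inoc, tps, sep = "_")
      ctrl_cells <- paste(ctrl, tps, sep = "_")
      window <- tps >= contin_t0
      inoc_m <- mm[rec$locus_id, inoc_cells]
      ctrl_m <- mm[rec$locus_id, ctrl_cells]
      irreversible <-
        all(inoc_m[window] == l, na.rm = FALSE) &&
        all(ctrl_m == f) &&
        all(is.na(inoc_m[!window]) | inoc_m[!window] == f)
      rec$category <- if (isTRUE(irreversible)) "irreversible_inoculated"
        else "continuous"
      rec$switch_times <- list(T_)
      out[[length(out) + 1L]] <- rec
    } else if (length(T_) == 1L) {
      rec$category <- "stage_specific"
      rec$switch_times <- list(T_)
      out[[length(out) + 1L]] <- rec
    } else {
      for (t_ in T_) {
        r2 <- rec
        r2$category <- "stage_specific"
        r2$switch_times <- list(t_)
        out[[length(out) + 1L]] <- r2
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- dplyr::mutate(switches, category = character(0),
                         switch_times = list())
  }
  attr(res, "major_matrix") <- mm
  res
}

#' Exact paired Wilcoxon signed-rank test (tie-aware)
#'
#' Signed-rank test on paired differences with average ranks under ties
#' and zero differences dropped.  For n <= `exact_max` non-zero pairs the
#' exact two-sided p-value is computed from the full sign-flip
#' distribution (dynamic programming over doubled ranks, so tied ranks
#' are handled exactly); larger n uses the normal approximation with
#' continuity correction and the usual tie variance correction.
#'
#' @param x,y paired numeric vectors.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_nonzero`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of V over all 2^n sign assignments; double ranks so
    # average ranks become integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)   # dist[s+1] = #assignments with sum = s
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(rep(0, rk), dist[seq_len(total + 1L - rk)])
      dist <- dist + shifted
    }
    probs <- dist / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = V, p_value = p, n_nonzero = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, p_value = p, n_nonzero = n, method = "normal_approx")
}

#' Compare former and latter switch isoforms
#'
#' Spliced transcript lengths and CDS lengths of the former versus latter
#' isoform of each switch, with paired two-sided Wilcoxon signed-rank
#' tests ([wilcoxon_signed_rank()]).  Fewer than `min_pairs` CDS pairs
#' sets a low-power warning flag.
#'
#' @param switches switch tibble (needs former/latter columns).
#' @param tx `transcript_models` tibble (CDS spans required for the CDS
#'   comparison).
#' @param min_pairs low-power threshold (default 5).
#' @return list with `table` (per-switch lengths), `p_transcript_length`,
#'   `p_cds_length`, `low_power`.
#' @export
compare_former_latter <- function(switches, tx, min_pairs = 5L) {
  lens <- transcript_lengths(tx)
  cl <- cds_lengths(tx)
  tab <- tibble::tibble(
    locus_id = switches$locus_id,
    former = switches$former, latter = switches$latter,
    transcript_length_former = unname(lens[switches$former]),
    transcript_length_latter = unname(lens[switches$latter]),
    cds_length_former = unname(cl[switches$former]),
    cds_length_latter = unname(cl[switches$latter])
  )
  ok <- !is.na(tab$cds_length_former) & !is.na(tab$cds_length_latter)
  p_len <- wilcoxon_signed_rank(tab$transcript_length_former,
                                tab$transcript_length_latter)
  p_cds <- if (any(ok)) {
    wilcoxon_signed_rank(tab$cds_length_former[ok], tab$cds_length_latter[ok])
  } else {
    list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L,
         method = "degenerate")
  }
  list(table = tab,
       p_transcript_length = p_len$p_value,
       p_cds_length = p_cds$p_value,
       low_power = sum(ok) < min_pairs)
}
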