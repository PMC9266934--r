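#' Filter lncRNA candidates
#'
#' Retains transcripts labelled non-coding whose longest ORF is at most
#' `max_orf_aa` amino acids (strictly-greater ORFs are removed, per the
#' "ORF > 100 aa" exclusion rule).  ORF length comes from the label table
#' (`orf_aa` column) when present, otherwise from a longest-ORF scan of
#' the supplied transcript sequence; a transcript with neither is an
#' error.  An optional precomputed exclusion list (e.g. protein-similarity
#' hits) removes further transcripts.
#'
#' @param tx `transcript_models` tibble.
#' @param coding_labels tibble (transcript_id, label in
#'   `coding`/`noncoding`, optional orf_aa).
#' @param sequences optional named character vector of spliced sequences.
#' @param exclusion_list optional transcript ids to drop.
#' @param max_orf_aa ORF length cutoff in amino acids (default 100).
#' @return character vector of candidate transcript ids.
#' @export
filter_lnc_candidates <- function(tx, coding_labels, sequences = NULL,
                                  exclusion_list = NULL, max_orf_aa = 100L) {
  lab <- coding_labels[match(tx$transcript_id, coding_labels$transcript_id), ,
                       drop = FALSE]
  noncoding <- !is.na(lab$label) & lab$label == "noncoding"
  orf_aa <- rep(NA_real_, nrow(tx))
  if ("orf_aa" %in% names(lab)) orf_aa <- as.numeric(lab$orf_aa)
  need <- which(noncoding & is.na(orf_aa))
  for (i in need) {
    id <- tx$transcript_id[i]
    if (is.null(sequences) || is.na(sequences[id])) {
      stop("transcript ", id, " lacks both an ORF label and a sequence")
    }
    orf <- find_orf(sequences[[id]], min_orf_nt = 0L)
    orf_aa[i] <- if (orf$cds_length > 0) orf$cds_length / 3 - 1 else 0
  }
  keep <- noncoding & orf_aa <= max_orf_aa
  ids <- tx$transcript_id[keep]
  setdiff(ids, exclusion_list)
}

span_of <- function(tx, i) {
  ex <- tx$exons[[i]]
  c(ex[1L, 1L], ex[nrow(ex), 2L])
}

exonic_overlap_nt <- function(ex1, ex2) {
  ov <- 0L
  for (i in seq_len(nrow(ex1))) {
    ov <- ov + sum(pmax(0L, pmin(ex1[i, 2], ex2[, 2]) -
                          pmax(ex1[i, 1], ex2[, 1])))
  }
  ov
}

#' Positional classification of one lncRNA against a protein-coding
#' annotation
#'
#' Priority order: antisense > sense_overlapping > proximal > intergenic,
#' with span overlap deciding overlap categories, exon-exon overlap
#' deciding the exonic/intronic subcategory, and transcript-boundary
#' distance (irrespective of strand) deciding proximal (<= `linc_distance`
#' nt) versus intergenic (lincRNA, > `linc_distance` nt).  Proximal
#' subcategories: `bidirectional_promoter` when the partner lies on the
#' opposite strand with the two 5' ends facing each other (divergent
#' orientation), otherwise `intergenic_proximal_upstream`/`_downstream`
#' relative to the partner's orientation.  Partner: for antisense lncRNAs
#' the maximally exon-overlapping anti-strand PC transcript; otherwise the
#' nearest PC transcript (ties by smaller distance, then towards the
#' lncRNA 5' side, then lexicographic id).
#'
#' @param lnc single-row `transcript_models` tibble.
#' @param pc_tx protein-coding `transcript_models` tibble.
#' @param linc_distance distance rule in nt (default 2000).
#' @return one-row tibble (transcript_id, category, subcategory,
#'   partner_pc_transcript, distance_to_partner).
#' @export
classify_lnc <- function(lnc, pc_tx, linc_distance = 2000L) {
  stopifnot(nrow(lnc) == 1L)
  lex <- lnc$exons[[1L]]
  lspan <- c(lex[1L, 1L], lex[nrow(lex), 2L])
  same_chr <- which(pc_tx$chrom == lnc$chrom)
  res <- function(category, subcategory, partner, distance) {
    tibble::tibble(transcript_id = lnc$transcript_id, category = category,
                   subcategory = subcategory,
                   partner_pc_transcript = partner,
                   distance_to_partner = as.integer(distance))
  }
  if (!length(same_chr)) return(res("intergenic", "lincRNA_distal",
                                    NA_character_, NA_integer_))
  spans <- t(vapply(same_chr, function(i) span_of(pc_tx, i), integer(2)))
  ov_span <- pmin(spans[, 2], lspan[2]) - pmax(spans[, 1], lspan[1])
  anti <- pc_tx$strand[same_chr] != lnc$strand
  overlapping <- ov_span > 0L

  if (any(overlapping & anti)) {
    idx <- same_chr[overlapping & anti]
    ex_ov <- vapply(idx, function(i) exonic_overlap_nt(lex, pc_tx$exons[[i]]),
                    integer(1))
    best <- idx[order(-ex_ov, pc_tx$transcript_id[idx])][1L]
    sub <- if (max(ex_ov) > 0L) "lncNAT_exonic" else "lncNAT_intronic"
    return(res("antisense", sub, pc_tx$transcript_id[best], 0L))
  }
  if (any(overlapping & !anti)) {
    idx <- same_chr[overlapping & !anti]
    ex_ov <- vapply(idx, function(i) exonic_overlap_nt(lex, pc_tx$exons[[i]]),
                    integer(1))
    best <- idx[order(-ex_ov, pc_tx$transcript_id[idx])][1L]
    sub <- if (max(ex_ov) > 0L) "sense_exonic_overlap" else "sense_intronic"
    return(res("sense_overlapping", sub, pc_tx$transcript_id[best], 0L))
  }
  # no overlap: nearest by boundary distance
  dist <- ifelse(spans[, 1] >= lspan[2], spans[, 1] - lspan[2],
                 lspan[1] - spans[, 2])
  # tie-break: smaller distance, then partner on the lncRNA 5' side, then id
  on_5prime_side <- if (lnc$strand == "+") spans[, 2] <= lspan[1] else
    spans[, 1] >= lspan[2]
  ord <- order(dist, !on_5prime_side, pc_tx$transcript_id[same_chr])
  best_rel <- ord[1L]
  best <- same_chr[best_rel]
  d <- dist[best_rel]
  partner <- pc_tx$transcript_id[best]
  if (d > linc_distance) {
    return(res("intergenic", "lincRNA_distal", partner, d))
  }
  pstrand <- pc_tx$strand[best]
  pspan <- spans[best_rel, ]
  lnc_upstream_of_pc <- if (pstrand == "+") lspan[2] <= pspan[1] else
    lspan[1] >= pspan[2]
  # divergent orientation: the two 5' ends face each other across the gap
  facing <- if (pstrand == "+") {
    lnc$strand == "-" && lspan[2] <= pspan[1]
  } else {
    lnc$strand == "+" && lspan[1] >= pspan[2]
  }
  sub <- if (facing) "bidirectional_promoter"
    else if (lnc_upstream_of_pc) "intergenic_proximal_upstream"
    else "intergenic_proximal_downstream"
  res("proximal", sub, partner, d)
}

#' Classify every lncRNA candidate
#' @param lnc_tx `transcript_models` tibble of candidates.
#' @param pc_tx protein-coding annotation.
#' @param ... passed to [classify_lnc()].
#' @return classification tibble, one row per candidate.
#' @export
classify_all_lnc <- function(lnc_tx, pc_tx, ...) {
  dplyr::bind_rows(lapply(seq_len(nrow(lnc_tx)), function(i) {
    classify_lnc(lnc_tx[i, , drop = FALSE], pc_tx, ...)
  }))
}

#' Compare structural/expression features of lncRNAs and mRNAs
#'
#' Exon count, maximum FPKM over samples, and spliced length per
#' transcript, with a two-sided Wilcoxon rank-sum test per feature.
#'
#' @param lnc_ids,mrna_ids transcript id sets (non-empty).
#' @param tx `transcript_models` tibble.
#' @param iso_expr isoform `expression_matrix`.
#' @return list with `features` tibble (transcript_id, group, exon_count,
#'   max_fpkm, length) and `tests` tibble (feature, p_value).
#' @export
lnc_feature_comparison <- function(lnc_ids, mrna_ids, tx, iso_expr) {
  if (!length(lnc_ids) || !length(mrna_ids)) stop("empty transcript set")
  ids <- c(lnc_ids, mrna_ids)
  grp <- rep(c("lncRNA", "mRNA"), c(length(lnc_ids), length(mrna_ids)))
  m <- match(ids, tx$transcript_id)
  stopifnot(!anyNA(m))
  feats <- tibble::tibble(
    transcript_id = ids, group = grp,
    exon_count = vapply(tx$exons[m], nrow, integer(1)),
    max_fpkm = apply(iso_expr$values[ids, , drop = FALSE], 1L, max),
    length = unname(transcript_lengths(tx)[ids])
  )
  tests <- dplyr::bind_rows(lapply(c("exon_count", "max_fpkm", "length"),
    function(f) {
      x <- feats[[f]][feats$group == "lncRNA"]
      y <- feats[[f]][feats$group == "mRNA"]
      p <- if (identical(sort(x), sort(y))) 1 else
        stats::wilcox.test(x, y, exact = FALSE)$p.value
      tibble::tibble(feature = f, p_value = p)
    }))
  list(features = feats, tests = tests)
}

#' Correlation between lncRNAs and their partner protein-coding
#' transcripts
#'
#' Spearman rho across all samples per (lncRNA, partner) pair, median per
#' category (antisense lncNATs versus intergenic lincRNAs), and a
#' two-sided rank-sum test between the two categories.  Partnerless
#' lncRNAs and pairs with a constant profile are excluded and counted.
#'
#' @param classifications output of [classify_all_lnc()].
#' @param iso_expr isoform `expression_matrix` containing both lncRNAs
#'   and partners.
#' @param de_lnc_set optional restriction to differentially expressed
#'   lncRNAs.
#' @return list with `pairs` tibble (lnc, partner, category, rho),
#'   `category_medians`, `p_between_categories`, `n_excluded`.
#' @export
lnc_pc_correlation <- function(classifications, iso_expr, de_lnc_set = NULL) {
  cl <- classifications
  if (!is.null(de_lnc_set)) cl <- cl[cl$transcript_id %in% de_lnc_set, ,
                                     drop = FALSE]
  excluded <- 0L
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    p <- cl$partner_pc_transcript[i]
    if (is.na(p) || !p %in% rownames(iso_expr$values) ||
        !cl$transcript_id[i] %in% rownames(iso_expr$values)) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    x <- iso_expr$values[cl$transcript_id[i], ]
    y <- iso_expr$values[p, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    tibble::tibble(lnc = cl$transcript_id[i], partner = p,
                   category = cl$category[i],
                   rho = stats::cor(x, y, method = "spearman"))
  })
  pairs <- dplyr::bind_rows(rows)
  med <- if (nrow(pairs)) {
    tapply(pairs$rho, pairs$category, stats::median)
  } else numeric(0)
  a <- pairs$rho[pairs$category == "antisense"]
  b <- pairs$rho[pairs$category == "intergenic"]
  p_bet <- if (length(a) && length(b)) {
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  } else NA_real_
  list(pairs = pairs, category_medians = med,
       p_between_categories = p_bet, n_excluded = excluded)
}
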