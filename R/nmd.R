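#' Find the best open reading frame in a spliced transcript sequence
#'
#' Scans all three sense-strand frames for ATG-to-stop ORFs (stop codon
#' included in the ORF), keeps the longest one of at least `min_orf_nt`
#' nucleotides, breaking ties towards the 5'-most start.  Upstream ORFs
#' (uORFs) are ATG-initiated ORFs of at least `min_uorf_nt` nucleotides
#' lying entirely within the 5' UTR of the chosen main ORF.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param min_orf_nt minimum main-ORF length in nt, stop codon included
#'   (default 30).
#' @param min_uorf_nt minimum uORF length in nt (default 9).
#' @return list with `has_orf`, `orf_start`, `orf_end` (0-based half-open
#'   spliced offsets), `cds_length`, `utr5_length`, `utr3_length`, and a
#'   `uorfs` tibble (start, end).  Without an ORF, `cds_length` is 0 and
#'   the UTR fields are `NA`.
#' @export
find_orf <- function(sequence, min_orf_nt = 30L, min_uorf_nt = 9L) {
  s <- toupper(sequence)
  n <- nchar(s)
  orfs <- all_orfs(s)
  keep <- orfs[orfs$length >= min_orf_nt, , drop = FALSE]
  if (!nrow(keep)) {
    return(list(has_orf = FALSE, orf_start = NA_integer_, orf_end = NA_integer_,
                cds_length = 0L, utr5_length = NA_integer_,
                utr3_length = NA_integer_,
                uorfs = tibble::tibble(start = integer(0), end = integer(0))))
  }
  best <- keep[order(-keep$length, keep$start), , drop = FALSE][1L, ]
  u <- orfs[orfs$length >= min_uorf_nt & orfs$end <= best$start, , drop = FALSE]
  list(
    has_orf = TRUE,
    orf_start = best$start, orf_end = best$end,
    cds_length = best$length,
    utr5_length = best$start,
    utr3_length = n - best$end,
    uorfs = tibble::tibble(start = u$start, end = u$end)
  )
}

# every ATG..stop ORF (stop included), 0-based half-open offsets
all_orfs <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (f in 0:2) {
    starts_cod <- seq.int(f + 1L, n - 2L, by = 3L)
    if (length(starts_cod) == 0L) next
    codons <- paste0(ch[starts_cod], ch[starts_cod + 1L], ch[starts_cod + 2L])
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    stop_idx <- which(is_stop)
    for (ai in which(is_atg)) {
      nxt <- stop_idx[stop_idx >= ai]
      if (!length(nxt)) next
      st <- starts_cod[ai] - 1L               # 0-based
      en <- starts_cod[nxt[1L]] + 2L          # end of stop codon, half-open
      rows[[length(rows) + 1L]] <- c(st, en)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0)))
  }
  m <- do.call(rbind, rows)
  tibble::tibble(start = m[, 1], end = m[, 2], length = m[, 2] - m[, 1])
}

#' Map a genomic position to spliced transcript coordinates
#'
#' @param tx single-row `transcript_models` tibble.
#' @param genomic_position 0-based genomic offset inside an exon.
#' @return 0-based spliced offset (0 = transcript 5' end; on the minus
#'   strand that is the highest genomic exonic coordinate).
#' @export
map_to_transcript_coords <- function(tx, genomic_position) {
  stopifnot(nrow(tx) == 1L)
  ex <- tx$exons[[1L]]
  hit <- which(genomic_position >= ex[, 1] & genomic_position < ex[, 2])
  if (!length(hit)) {
    stop("position ", genomic_position, " not exonic in ", tx$transcript_id)
  }
  w <- ex[, 2] - ex[, 1]
  if (tx$strand == "+") {
    before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
    as.integer(before + genomic_position - ex[hit, 1])
  } else {
    after <- if (hit < nrow(ex)) sum(w[(hit + 1L):nrow(ex)]) else 0L
    as.integer(after + ex[hit, 2] - 1L - genomic_position)
  }
}

#' Map a spliced transcript offset back to a genomic position
#'
#' Inverse of [map_to_transcript_coords()].
#'
#' @param tx single-row `transcript_models` tibble.
#' @param offset 0-based spliced offset in `[0, transcript length)`.
#' @return 0-based genomic position.
#' @export
map_from_transcript_coords <- function(tx, offset) {
  stopifnot(nrow(tx) == 1L)
  ex <- tx$exons[[1L]]
  w <- ex[, 2] - ex[, 1]
  total <- sum(w)
  if (offset < 0L || offset >= total) {
    stop("offset ", offset, " outside transcript ", tx$transcript_id)
  }
  if (tx$strand == "-") {
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    w <- rev(w)
  }
  cum <- cumsum(w)
  i <- which(offset < cum)[1L]
  within <- offset - (if (i > 1L) cum[i - 1L] else 0L)
  if (tx$strand == "+") {
    as.integer(ex[i, 1] + within)
  } else {
    as.integer(ex[i, 2] - 1L - within)
  }
}

#' Exon-exon junction offsets in spliced coordinates
#'
#' @param tx single-row `transcript_models` tibble.
#' @return integer vector of spliced offsets (nt 5' of each junction);
#'   empty for mono-exon transcripts.
#' @export
transcript_junction_offsets <- function(tx) {
  stopifnot(nrow(tx) == 1L)
  ex <- tx$exons[[1L]]
  if (nrow(ex) < 2L) return(integer(0))
  w <- ex[, 2] - ex[, 1]
  if (tx$strand == "-") w <- rev(w)
  cumsum(w)[-length(w)]
}

#' ORF annotation from an annotated genomic CDS span
#'
#' Converts the transcript's genomic CDS span to spliced coordinates,
#' yielding the same structure as [find_orf()] (without uORF calls, which
#' require sequence).
#'
#' @param tx single-row `transcript_models` tibble with `cds_start`/`cds_end`.
#' @return ORF annotation list.
#' @export
orf_from_cds <- function(tx) {
  stopifnot(nrow(tx) == 1L)
  if (is.na(tx$cds_start)) stop("transcript ", tx$transcript_id, " has no CDS")
  a <- map_to_transcript_coords(tx, tx$cds_start)
  b <- map_to_transcript_coords(tx, tx$cds_end - 1L)
  orf_start <- min(a, b)
  orf_end <- max(a, b) + 1L
  total <- sum(tx$exons[[1L]][, 2] - tx$exons[[1L]][, 1])
  list(has_orf = TRUE, orf_start = orf_start, orf_end = orf_end,
       cds_length = orf_end - orf_start,
       utr5_length = orf_start, utr3_length = total - orf_end,
       uorfs = tibble::tibble(start = integer(0), end = integer(0)))
}

#' Screen a transcript for NMD-predictive features
#'
#' Rule-based premature-termination-codon screen:
#' \itemize{
#'  \item `long_utr3`: spliced 3' UTR strictly longer than `utr3_threshold`
#'    nt (default 580, the third quartile convention);
#'  \item `ptc_rule`: at least one exon-exon junction 3' of the stop codon
#'    AND the distance from the stop to the last junction strictly greater
#'    than `eej_distance` nt (default 50);
#'  \item `nmd_candidate`: `long_utr3 OR ptc_rule` (both components are
#'    always reported so users can recombine).
#' }
#'
#' @param tx single-row `transcript_models` tibble.
#' @param orf ORF annotation from [find_orf()] or [orf_from_cds()].
#' @param utr3_threshold,eej_distance rule thresholds (strict inequalities).
#' @return tibble row with the flags, `stop_to_last_eej` (`NA` when no
#'   junction lies 3' of the stop) and `has_uorf`.
#' @export
screen_nmd <- function(tx, orf, utr3_threshold = 580L, eej_distance = 50L) {
  stopifnot(nrow(tx) == 1L)
  if (!isTRUE(orf$has_orf) || orf$cds_length == 0L) {
    stop("NMD screen undefined without a stop codon: ", tx$transcript_id)
  }
  j <- transcript_junction_offsets(tx)
  downstream <- j[j > orf$orf_end]
  junction_in_utr3 <- length(downstream) > 0L
  stop_to_last_eej <- if (junction_in_utr3) max(j) - orf$orf_end else NA_integer_
  long_utr3 <- orf$utr3_length > utr3_threshold
  ptc_rule <- junction_in_utr3 && stop_to_last_eej > eej_distance
  tibble::tibble(
    transcript_id = tx$transcript_id,
    utr3_length = orf$utr3_length,
    long_utr3 = long_utr3,
    junction_in_utr3 = junction_in_utr3,
    stop_to_last_eej = as.integer(stop_to_last_eej),
    ptc_rule = ptc_rule,
    nmd_candidate = long_utr3 || ptc_rule,
    has_uorf = nrow(orf$uorfs) > 0L
  )
}

#' NMD screen over all CDS-annotated transcripts of a model table
#' @param tx `transcript_models` tibble.
#' @param ... passed to [screen_nmd()].
#' @return tibble with one row per CDS-bearing transcript.
#' @export
screen_nmd_all <- function(tx, ...) {
  idx <- which(!is.na(tx$cds_start))
  dplyr::bind_rows(lapply(idx, function(i) {
    one <- tx[i, , drop = FALSE]
    screen_nmd(one, orf_from_cds(one), ...)
  }))
}

#' Third quartile of 3' UTR lengths
#'
#' Linear interpolation between order statistics (the type-7 convention of
#' [stats::quantile()]); exposed so the long-3'UTR threshold can be
#' re-derived on any dataset.
#'
#' @param utr3_lengths numeric vector (n >= 4).
#' @return Q3 as a numeric scalar.
#' @export
utr3_quartile <- function(utr3_lengths) {
  utr3_lengths <- utr3_lengths[!is.na(utr3_lengths)]
  if (length(utr3_lengths) < 4L) stop("need at least 4 3' UTR lengths")
  unname(stats::quantile(utr3_lengths, 0.75, type = 7))
}
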