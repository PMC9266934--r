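#' Transcript models
#'
#' A `transcript_models` object is a tibble with one row per transcript and
#' columns:
#' \describe{
#'   \item{transcript_id}{character, unique}
#'   \item{locus_id}{character; the gene/locus the transcript belongs to}
#'   \item{chrom}{character}
#'   \item{strand}{`"+"` or `"-"`}
#'   \item{biotype}{one of `"coding"`, `"lncRNA"`, `"unknown"`}
#'   \item{cds_start`,`cds_end}{genomic span of the coding region
#'     (0-based half-open), `NA` when absent}
#'   \item{exons}{list column; each element an integer matrix with columns
#'     `start`, `end`, rows sorted by start, 0-based half-open, pairwise
#'     disjoint}
#' }
#' All coordinates are 0-based half-open internally; GTF/GFF3 emission
#' converts to the 1-based inclusive convention of those formats.
#'
#' @param transcript_id,locus_id,chrom,strand,biotype character vectors
#'   (recycled where length 1).
#' @param exons list of numeric matrices (columns start, end).
#' @param cds_start,cds_end optional genomic CDS span per transcript.
#' @return A validated `transcript_models` tibble.
#' @export
transcript_models <- function(transcript_id, locus_id, chrom, strand, exons,
                              cds_start = NA_integer_, cds_end = NA_integer_,
                              biotype = "coding") {
  n <- length(transcript_id)
  tx <- tibble::tibble(
    transcript_id = as.character(transcript_id),
    locus_id      = rep_len(as.character(locus_id), n),
    chrom         = rep_len(as.character(chrom), n),
    strand        = rep_len(as.character(strand), n),
    biotype       = rep_len(as.character(biotype), n),
    cds_start     = rep_len(as.integer(cds_start), n),
    cds_end       = rep_len(as.integer(cds_end), n),
    exons         = unname(lapply(exons, as_exon_matrix))
  )
  class(tx) <- c("transcript_models", class(tx))
  validate_transcripts(tx)
  tx
}

as_exon_matrix <- function(m) {
  m <- matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1]), , drop = FALSE]
}

#' Validate a transcript-model table
#'
#' Checks the container invariants: exons sorted and pairwise disjoint,
#' strictly positive widths, known strand, CDS (when present) contained in
#' the exonic union.
#'
#' @param tx a `transcript_models` tibble.
#' @return `tx` invisibly; stops with the offending transcript id otherwise.
#' @export
validate_transcripts <- function(tx) {
  stopifnot(is.data.frame(tx), !anyDuplicated(tx$transcript_id))
  if (!all(tx$strand %in% c("+", "-"))) {
    bad <- tx$transcript_id[!tx$strand %in% c("+", "-")]
    stop("unknown strand for transcript(s): ", paste(bad, collapse = ", "))
  }
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    id <- tx$transcript_id[i]
    if (nrow(ex) == 0L || any(ex[, 2] <= ex[, 1])) {
      stop("empty or zero-width exon in transcript ", id)
    }
    if (nrow(ex) > 1L) {
      if (is.unsorted(ex[, 1], strictly = TRUE) ||
          any(ex[-1L, 1] < ex[-nrow(ex), 2])) {
        stop("unsorted or overlapping exons in transcript ", id)
      }
    }
    cs <- tx$cds_start[i]
    if (!is.na(cs)) {
      ce <- tx$cds_end[i]
      if (is.na(ce) || ce <= cs ||
          cs < ex[1, 1] || ce > ex[nrow(ex), 2] ||
          !any(cs >= ex[, 1] & cs < ex[, 2]) ||
          !any(ce > ex[, 1] & ce <= ex[, 2])) {
        stop("CDS span outside exonic bounds in transcript ", id)
      }
    }
  }
  invisible(tx)
}

#' Spliced transcript lengths
#'
#' @param tx a `transcript_models` tibble.
#' @return named integer vector of summed exon widths.
#' @export
transcript_lengths <- function(tx) {
  stats::setNames(
    vapply(tx$exons, function(e) sum(e[, 2] - e[, 1]), integer(1)),
    tx$transcript_id
  )
}

#' Genomic span of each transcript
#' @param tx a `transcript_models` tibble.
#' @return tibble with transcript_id, chrom, strand, start, end.
#' @export
transcript_spans <- function(tx) {
  tibble::tibble(
    transcript_id = tx$transcript_id,
    chrom = tx$chrom,
    strand = tx$strand,
    start = vapply(tx$exons, function(e) e[1L, 1L], integer(1)),
    end   = vapply(tx$exons, function(e) e[nrow(e), 2L], integer(1))
  )
}

#' Spliced CDS length of each transcript
#'
#' Sums the overlap of the genomic CDS span with the exon chain; `NA` for
#' transcripts without an annotated CDS.
#'
#' @param tx a `transcript_models` tibble.
#' @return named integer vector.
#' @export
cds_lengths <- function(tx) {
  out <- vapply(seq_len(nrow(tx)), function(i) {
    cs <- tx$cds_start[i]
    if (is.na(cs)) return(NA_integer_)
    ce <- tx$cds_end[i]
    ex <- tx$exons[[i]]
    sum(pmax(0L, pmin(ex[, 2], ce) - pmax(ex[, 1], cs)))
  }, integer(1))
  stats::setNames(out, tx$transcript_id)
}

tx_to_granges <- function(tx) {
  nex <- vapply(tx$exons, nrow, integer(1))
  allex <- do.call(rbind, tx$exons)
  GenomicRanges::GRanges(
    seqnames = rep(tx$chrom, nex),
    ranges = IRanges::IRanges(start = allex[, 1] + 1L, end = allex[, 2]),
    strand = rep(tx$strand, nex),
    transcript_id = rep(tx$transcript_id, nex),
    txi = rep(seq_len(nrow(tx)), nex)
  )
}

#' Read transcript models from GTF or GFF3
#'
#' Exon features carrying `transcript_id` (GTF) are assembled into
#' transcript models; `CDS` features define the genomic coding span.  GFF3
#' files written by [write_gtf()] carry the same attribute names and parse
#' to the identical internal representation.
#'
#' @param path file path; dialect chosen from the extension (`.gff3`/`.gff`
#'   parsed as GFF3, anything else as GTF) unless `format` is given.
#' @param format `"gtf"` or `"gff3"`, overriding the extension.
#' @return a `transcript_models` tibble.
#' @export
read_gtf <- function(path, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (!"transcript_id" %in% names(df)) stop("no transcript_id attribute in ", path)
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  ids <- unique(ex$transcript_id)
  idx <- split(seq_len(nrow(ex)), ex$transcript_id)[ids]
  get1 <- function(v) vapply(idx, function(i) as.character(v[i[1L]]), character(1))
  exons <- lapply(idx, function(i) {
    cbind(start = ex$start[i] - 1L, end = ex$end[i])
  })
  cds_start <- rep(NA_integer_, length(ids))
  cds_end <- rep(NA_integer_, length(ids))
  if (nrow(cds)) {
    cs <- tapply(cds$start, cds$transcript_id, min) - 1L
    ce <- tapply(cds$end, cds$transcript_id, max)
    m <- match(ids, names(cs))
    cds_start <- ifelse(is.na(m), NA_integer_, as.integer(cs[m]))
    cds_end <- ifelse(is.na(m), NA_integer_, as.integer(ce[m]))
  }
  biotype <- if ("transcript_biotype" %in% names(ex)) get1(ex$transcript_biotype) else "unknown"
  biotype[is.na(biotype)] <- "unknown"
  transcript_models(
    transcript_id = ids,
    locus_id = get1(ex$gene_id),
    chrom = get1(ex$seqnames),
    strand = get1(ex$strand),
    exons = exons,
    cds_start = cds_start, cds_end = cds_end,
    biotype = biotype
  )
}

#' Write transcript models to GTF or GFF3
#'
#' @param tx a `transcript_models` tibble.
#' @param path output path.
#' @param format `"gtf"` (default) or `"gff3"`.
#' @return `path` invisibly.
#' @export
write_gtf <- function(tx, path, format = c("gtf", "gff3")) {
  format <- match.arg(format)
  validate_transcripts(tx)
  gr <- tx_to_granges(tx)
  i <- gr$txi
  gr$type <- "exon"
  gr$gene_id <- tx$locus_id[i]
  gr$transcript_biotype <- tx$biotype[i]
  gr$txi <- NULL
  # CDS rows: genomic span clipped to each overlapping exon, with phase
  cds_rows <- list()
  for (k in which(!is.na(tx$cds_start))) {
    ex <- tx$exons[[k]]
    s <- pmax(ex[, 1], tx$cds_start[k])
    e <- pmin(ex[, 2], tx$cds_end[k])
    keep <- e > s
    if (!any(keep)) next
    s <- s[keep]; e <- e[keep]
    w <- e - s
    # phase per piece in transcript (5'->3') order
    ord <- if (tx$strand[k] == "+") seq_along(w) else rev(seq_along(w))
    before <- c(0L, cumsum(w[ord]))[seq_along(w)]
    phase <- integer(length(w))
    phase[ord] <- (3L - before %% 3L) %% 3L
    piece <- GenomicRanges::GRanges(
      seqnames = tx$chrom[k],
      ranges = IRanges::IRanges(start = s + 1L, end = e),
      strand = tx$strand[k],
      transcript_id = tx$transcript_id[k],
      type = "CDS",
      gene_id = tx$locus_id[k],
      transcript_biotype = tx$biotype[k]
    )
    piece$phase <- phase
    cds_rows[[length(cds_rows) + 1L]] <- piece
  }
  if (length(cds_rows)) {
    cds_gr <- do.call(c, cds_rows)
    gr$phase <- NA_integer_
    gr <- c(gr, cds_gr)
  }
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Group transcripts into loci by exonic overlap
#'
#' Single-linkage grouping: two transcripts belong to the same locus iff
#' they are connected by a chain of pairwise exonic overlaps of at least
#' `min_overlap` nt (on the same strand when `require_same_strand` is TRUE).
#' Returns a partition: every transcript appears in exactly one locus.
#'
#' @param tx a `transcript_models` tibble.
#' @param require_same_strand logical; group only within strand (default).
#' @param min_overlap minimum exonic overlap in nt (default 1).
#' @return tibble with locus_id, chrom, strand, start, end and a
#'   `transcript_ids` list column.
#' @export
group_into_loci <- function(tx, require_same_strand = TRUE, min_overlap = 1L) {
  gr <- tx_to_granges(tx)
  if (!require_same_strand) GenomicRanges::strand(gr) <- "*"
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = min_overlap)
  a <- gr$txi[S4Vectors::queryHits(hits)]
  b <- gr$txi[S4Vectors::subjectHits(hits)]
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(tx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(nrow(tx))]
  sp <- transcript_spans(tx)
  out <- lapply(split(seq_len(nrow(tx)), comp), function(i) {
    tibble::tibble(
      chrom = tx$chrom[i[1L]],
      strand = if (length(unique(tx$strand[i])) == 1L) tx$strand[i[1L]] else "*",
      start = min(sp$start[i]),
      end = max(sp$end[i]),
      transcript_ids = list(tx$transcript_id[i])
    )
  })
  out <- dplyr::bind_rows(out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$locus_id <- sprintf("LOC%05d", seq_len(nrow(out)))
  out[, c("locus_id", "chrom", "strand", "start", "end", "transcript_ids")]
}

#' Assign locus ids from a locus table back onto transcripts
#' @param tx a `transcript_models` tibble.
#' @param loci output of [group_into_loci()].
#' @return `tx` with `locus_id` replaced by the grouped assignment.
#' @export
assign_loci <- function(tx, loci) {
  map <- stats::setNames(
    rep(loci$locus_id, lengths(loci$transcript_ids)),
    unlist(loci$transcript_ids)
  )
  tx$locus_id <- unname(map[tx$transcript_id])
  tx
}

#' Isoforms-per-locus histogram
#'
#' @param loci output of [group_into_loci()], or a `transcript_models`
#'   tibble (grouped by its `locus_id` column).
#' @return tibble with `n_isoforms`, `n_loci`, `fraction` (fractions sum to
#'   1), plus attribute `multi_isoform_fraction`.
#' @export
isoforms_per_locus_histogram <- function(loci) {
  counts <- if ("transcript_ids" %in% names(loci)) {
    lengths(loci$transcript_ids)
  } else if ("locus_id" %in% names(loci)) {
    as.integer(table(loci$locus_id))
  } else {
    stop("need a locus table or transcript table")
  }
  if (!length(counts)) stop("empty input")
  tab <- table(counts)
  out <- tibble::tibble(
    n_isoforms = as.integer(names(tab)),
    n_loci = as.integer(tab),
    fraction = as.integer(tab) / length(counts)
  )
  attr(out, "multi_isoform_fraction") <- mean(counts > 1L)
  out
}

#' Exons-per-isoform statistics
#'
#' @param tx a `transcript_models` tibble.
#' @return list with `mean`, `single_exon_fraction` and a `histogram` tibble.
#' @export
exons_per_isoform_stats <- function(tx) {
  if (!nrow(tx)) stop("empty input")
  n <- vapply(tx$exons, nrow, integer(1))
  tab <- table(n)
  list(
    mean = mean(n),
    single_exon_fraction = mean(n == 1L),
    histogram = tibble::tibble(
      n_exons = as.integer(names(tab)),
      n_transcripts = as.integer(tab),
      fraction = as.integer(tab) / length(n)
    )
  )
}

intron_chain <- function(ex) {
  if (nrow(ex) < 2L) return(matrix(integer(0), ncol = 2))
  cbind(unname(ex[-nrow(ex), 2L]), unname(ex[-1L, 1L]))
}

chain_key <- function(ic) paste(ic[, 1], ic[, 2], sep = "-", collapse = ";")

#' Classify an isoform against a reference annotation
#'
#' Structural-category assignment in the style common for long-read
#' transcript QC, applied with a deterministic priority order:
#' \itemize{
#'  \item `full_splice_match`: intron chain identical to a reference
#'    transcript (mono-exon: >= `mono_exon_overlap` reciprocal span overlap
#'    with a mono-exon reference transcript);
#'  \item `incomplete_splice_match`: intron chain a contiguous sub-chain of
#'    a reference transcript's chain;
#'  \item `novel_in_catalog`: all junctions known in the reference, new
#'    combination;
#'  \item `novel_not_in_catalog`: >= 1 novel junction at a locus with
#'    same-strand exonic reference overlap;
#'  \item `fusion_or_other`: same-strand exonic overlap with more than one
#'    reference locus;
#'  \item `genic_overlap`: same-strand exonic overlap not qualifying above;
#'  \item `antisense`: exonic overlap only on the opposite strand;
#'  \item `intergenic`: no exonic overlap with any reference transcript.
#' }
#'
#' @param isoform single-row `transcript_models` tibble (or the full table,
#'   classified row-wise via [classify_all_vs_reference()]).
#' @param reference `transcript_models` tibble of reference annotation.
#' @param mono_exon_overlap reciprocal-overlap fraction for mono-exon
#'   matching (default 0.5).
#' @return character scalar category label.
#' @export
classify_vs_reference <- function(isoform, reference, mono_exon_overlap = 0.5) {
  stopifnot(nrow(isoform) == 1L)
  ex <- isoform$exons[[1L]]
  same <- reference$chrom == isoform$chrom & reference$strand == isoform$strand
  anti_strand <- if (isoform$strand == "+") "-" else "+"
  overlaps_exonic <- function(ref_rows) {
    vapply(ref_rows, function(j) {
      re <- reference$exons[[j]]
      any(outer(ex[, 1], re[, 2], `<`) & outer(ex[, 2], re[, 1], `>`))
    }, logical(1))
  }
  same_idx <- which(same)
  same_ov <- same_idx[overlaps_exonic(same_idx)]
  anti_idx <- which(reference$chrom == isoform$chrom &
                      reference$strand == anti_strand)
  anti_ov <- anti_idx[overlaps_exonic(anti_idx)]

  ic <- intron_chain(ex)
  if (nrow(ic) == 0L) {
    # mono-exon: span-overlap comparison
    for (j in same_ov) {
      re <- reference$exons[[j]]
      if (nrow(re) != 1L) next
      ov <- min(ex[1, 2], re[1, 2]) - max(ex[1, 1], re[1, 1])
      if (ov >= mono_exon_overlap * (ex[1, 2] - ex[1, 1]) &&
          ov >= mono_exon_overlap * (re[1, 2] - re[1, 1])) {
        return("full_splice_match")
      }
    }
    if (length(same_ov)) {
      if (length(unique(reference$locus_id[same_ov])) > 1L) return("fusion_or_other")
      return("genic_overlap")
    }
    if (length(anti_ov)) return("antisense")
    return("intergenic")
  }

  key <- chain_key(ic)
  ref_chains <- lapply(same_ov, function(j) intron_chain(reference$exons[[j]]))
  ref_keys <- vapply(ref_chains, chain_key, character(1))
  if (any(ref_keys == key)) return("full_splice_match")
  # contiguous sub-chain of some reference chain
  for (rk in ref_keys) {
    parts <- strsplit(rk, ";", fixed = TRUE)[[1L]]
    n <- nrow(ic)
    if (length(parts) > n) {
      own <- strsplit(key, ";", fixed = TRUE)[[1L]]
      for (s in seq_len(length(parts) - n + 1L)) {
        if (identical(parts[s:(s + n - 1L)], own)) return("incomplete_splice_match")
      }
    }
  }
  ref_j <- unique(do.call(rbind, ref_chains))
  jn_known <- if (is.null(ref_j) || nrow(ref_j) == 0L) {
    rep(FALSE, nrow(ic))
  } else {
    paste(ic[, 1], ic[, 2]) %in% paste(ref_j[, 1], ref_j[, 2])
  }
  if (length(same_ov)) {
    if (all(jn_known)) return("novel_in_catalog")
    if (length(unique(reference$locus_id[same_ov])) > 1L) return("fusion_or_other")
    return("novel_not_in_catalog")
  }
  if (length(anti_ov)) return("antisense")
  "intergenic"
}

#' Classify every transcript against a reference
#' @param tx,reference `transcript_models` tibbles.
#' @param ... passed to [classify_vs_reference()].
#' @return tibble (transcript_id, category).
#' @export
classify_all_vs_reference <- function(tx, reference, ...) {
  tibble::tibble(
    transcript_id = tx$transcript_id,
    category = vapply(seq_len(nrow(tx)), function(i) {
      classify_vs_reference(tx[i, , drop = FALSE], reference, ...)
    }, character(1))
  )
}

#' Fraction of transcripts sharing at least one splice junction with a
#' reference annotation
#'
#' Mono-exon transcripts have no junctions and count as non-sharing.
#'
#' @param tx,reference `transcript_models` tibbles.
#' @return fraction in \[0, 1\].
#' @export
shared_junction_fraction <- function(tx, reference) {
  ref_set <- junction_key_set(reference)
  shares <- vapply(seq_len(nrow(tx)), function(i) {
    ic <- intron_chain(tx$exons[[i]])
    if (nrow(ic) == 0L) return(FALSE)
    any(paste(tx$chrom[i], tx$strand[i], ic[, 1], ic[, 2]) %in% ref_set)
  }, logical(1))
  mean(shares)
}

junction_key_set <- function(tx) {
  unique(unlist(lapply(seq_len(nrow(tx)), function(i) {
    ic <- intron_chain(tx$exons[[i]])
    if (nrow(ic) == 0L) return(character(0))
    paste(tx$chrom[i], tx$strand[i], ic[, 1], ic[, 2])
  })))
}

#' Sequencing-run library summary bookkeeping
#'
#' Reads a per-library summary table (TSV with columns `library_size_kb`,
#' `smrt_cells`, `polymerase_reads`, `flnc_reads`, `hq_isoforms`; one row per
#' size-fraction library plus optionally a `Total` row) and recomputes the
#' totals from the per-library rows.
#'
#' @param path TSV path; default: the library summary shipped with the
#'   package.
#' @return list with `per_library` tibble, computed `totals`, and
#'   `printed_totals` (the file's Total row, if present).
#' @export
read_library_summary <- function(path = system.file("extdata",
                                                    "isoseq_library_summary.tsv",
                                                    package = "isonodule")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  is_total <- tolower(tab$library_size_kb) == "total"
  per <- tab[!is_total, , drop = FALSE]
  num_cols <- c("smrt_cells", "polymerase_reads", "flnc_reads", "hq_isoforms")
  totals <- vapply(per[num_cols], function(x) sum(as.numeric(x)), numeric(1))
  printed <- if (any(is_total)) {
    vapply(tab[is_total, num_cols], as.numeric, numeric(1))
  } else NULL
  list(
    per_library = tibble::as_tibble(per),
    totals = totals,
    printed_totals = printed
  )
}
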