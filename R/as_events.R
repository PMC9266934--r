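#' Splice junctions of a transcript
#'
#' Introns are the gaps between consecutive exons.  Donor/acceptor sides are
#' strand-aware: for an intron `[s, e)` on the plus strand the donor is `s`
#' (end of the 5' exon) and the acceptor is `e`; on the minus strand the
#' roles are reversed.
#'
#' @param tx single-row `transcript_models` tibble, or an exon matrix plus
#'   `chrom`/`strand`.
#' @return tibble with chrom, strand, intron_start, intron_end, donor,
#'   acceptor; `n_exons - 1` rows.
#' @export
junctions_of <- function(tx) {
  stopifnot(nrow(tx) == 1L)
  ic <- intron_chain(tx$exons[[1L]])
  if (nrow(ic) == 0L) {
    return(tibble::tibble(
      chrom = character(0), strand = character(0),
      intron_start = integer(0), intron_end = integer(0),
      donor = integer(0), acceptor = integer(0)
    ))
  }
  plus <- tx$strand == "+"
  tibble::tibble(
    chrom = tx$chrom, strand = tx$strand,
    intron_start = ic[, 1], intron_end = ic[, 2],
    donor = if (plus) ic[, 1] else ic[, 2],
    acceptor = if (plus) ic[, 2] else ic[, 1]
  )
}

#' All splice junctions of a transcript set
#' @param tx `transcript_models` tibble.
#' @param unique_only drop duplicate junctions shared between isoforms.
#' @return tibble (chrom, strand, intron_start, intron_end).
#' @export
all_junctions <- function(tx, unique_only = TRUE) {
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    ic <- intron_chain(tx$exons[[i]])
    if (nrow(ic) == 0L) return(NULL)
    tibble::tibble(
      chrom = tx$chrom[i], strand = tx$strand[i],
      intron_start = ic[, 1], intron_end = ic[, 2]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (unique_only && nrow(out)) out <- dplyr::distinct(out)
  out
}

# interval helpers on [start, end) matrices -----------------------------------

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2
.contains_strict <- function(os, oe, is_, ie) os < is_ & ie < oe

empty_events <- function() {
  tibble::tibble(
    event_type = character(0), locus_id = character(0),
    chrom = character(0), strand = character(0),
    var_start = integer(0), var_end = integer(0),
    inclusion = list(), exclusion = list(),
    flank_left = integer(0), flank_right = integer(0)
  )
}

#' Classify the alternative-splicing events between two transcripts
#'
#' Pairwise event grammar over the five canonical types:
#' \itemize{
#'  \item IR: an intron of one transcript lies strictly inside an exon of
#'    the other (both boundaries interior).  Inclusion isoform = the one
#'    retaining the intron as exonic sequence.
#'  \item ES: an internal exon of one transcript whose two flanking introns
#'    have outer splice sites coinciding with a single intron of the other.
#'    Inclusion = the exon-containing isoform.
#'  \item A5SS/A3SS: two introns sharing exactly one boundary; strand-aware
#'    naming (A5SS: shared acceptor, differing donor; A3SS: shared donor,
#'    differing acceptor).  Inclusion = isoform with the shorter intron.
#'  \item MXE: each transcript holds exactly one of two non-overlapping
#'    internal exons with shared outer flanking splice sites.  Inclusion =
#'    isoform containing the 5' (transcript orientation) exon.
#' }
#' Structural differences inside the shared span matching none of these are
#' reported as one `complex` event per contiguous difference region.
#' Differences outside the shared genomic span (alternative start/end) are
#' not splicing events and are ignored.  Events are ordered left-to-right
#' by variable region.
#'
#' @param a,b single-row `transcript_models` tibbles on the same
#'   chromosome and strand.
#' @return event tibble (possibly empty): event_type, locus_id, chrom,
#'   strand, var_start, var_end, inclusion/exclusion id list columns,
#'   flank_left, flank_right.
#' @export
classify_pair <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (a$chrom != b$chrom || a$strand != b$strand) {
    stop("transcripts on different chrom/strand: ",
         a$transcript_id, " vs ", b$transcript_id)
  }
  exa <- a$exons[[1L]]; exb <- b$exons[[1L]]
  lo <- max(exa[1, 1], exb[1, 1])
  hi <- min(exa[nrow(exa), 2], exb[nrow(exb), 2])
  if (lo >= hi) return(empty_events())
  # clip both chains to the shared span
  clip <- function(ex) {
    s <- pmax(ex[, 1], lo); e <- pmin(ex[, 2], hi)
    keep <- e > s
    cbind(start = s[keep], end = e[keep])
  }
  ca <- clip(exa); cb <- clip(exb)
  ia <- intron_chain(ca); ib <- intron_chain(cb)
  key <- function(m) paste(m[, 1], m[, 2])
  ka <- key(ia); kb <- key(ib)
  ua <- ia[!(ka %in% kb), , drop = FALSE]  # introns unique to a
  ub <- ib[!(kb %in% ka), , drop = FALSE]
  if (nrow(ua) == 0L && nrow(ub) == 0L) return(empty_events())

  ida <- a$transcript_id; idb <- b$transcript_id
  plus <- a$strand == "+"
  ev <- list()
  used_a <- rep(FALSE, nrow(ua)); used_b <- rep(FALSE, nrow(ub))
  add <- function(type, vs, ve, inc, exc, fl = NA_integer_, fr = NA_integer_) {
    ev[[length(ev) + 1L]] <<- tibble::tibble(
      event_type = type, locus_id = a$locus_id,
      chrom = a$chrom, strand = a$strand,
      var_start = as.integer(vs), var_end = as.integer(ve),
      inclusion = list(inc), exclusion = list(exc),
      flank_left = as.integer(fl), flank_right = as.integer(fr)
    )
  }

  # --- IR: unique intron of one strictly inside an exon of the other
  ir_scan <- function(u, used, other_ex, inc_id, exc_id) {
    for (i in seq_len(nrow(u))) {
      if (used[i]) next
      s <- u[i, 1]; e <- u[i, 2]
      hit <- which(.contains_strict(other_ex[, 1], other_ex[, 2], s, e))
      if (length(hit)) {
        add("IR", s, e, inc_id, exc_id, s, e)
        used[i] <- TRUE
      }
    }
    used
  }
  # inclusion retains the intron as exonic: if a's intron is inside b's exon,
  # b retains -> inclusion = b
  used_a <- ir_scan(ua, used_a, cb, idb, ida)
  used_b <- ir_scan(ub, used_b, ca, ida, idb)

  # --- ES: internal exon of x flanked by introns matching one intron of y
  es_scan <- function(cx, ix, ux, usedx, uy, usedy, inc_id, exc_id) {
    if (nrow(cx) < 3L) return(list(usedx, usedy))
    kx <- key(ix); kux <- key(ux); kuy <- key(uy)
    for (k in 2:(nrow(cx) - 1L)) {
      l <- ix[k - 1L, ]; r <- ix[k, ]
      j <- which(uy[, 1] == l[1] & uy[, 2] == r[2])
      if (!length(j) || usedy[j[1L]]) next
      # exon k must not overlap the other's exons (it is skipped there)
      li <- which(kux == paste(l[1], l[2]))
      ri <- which(kux == paste(r[1], r[2]))
      if (!length(li) || !length(ri)) next
      if (usedx[li[1L]] || usedx[ri[1L]]) next
      add("ES", cx[k, 1], cx[k, 2], inc_id, exc_id, l[1], r[2])
      usedx[c(li[1L], ri[1L])] <- TRUE
      usedy[j[1L]] <- TRUE
    }
    list(usedx, usedy)
  }
  res <- es_scan(ca, ia, ua, used_a, ub, used_b, ida, idb)
  used_a <- res[[1L]]; used_b <- res[[2L]]
  res <- es_scan(cb, ib, ub, used_b, ua, used_a, idb, ida)
  used_b <- res[[1L]]; used_a <- res[[2L]]

  # --- MXE: one distinct internal exon each, shared outer flanks
  if (nrow(ca) >= 3L && nrow(cb) >= 3L) {
    for (k in 2:(nrow(ca) - 1L)) {
      for (m in 2:(nrow(cb) - 1L)) {
        xa <- ca[k, ]; xb <- cb[m, ]
        if (.overlaps(xa[1], xa[2], xb[1], xb[2])) next
        if (any(.overlaps(xa[1], xa[2], cb[, 1], cb[, 2]))) next
        if (any(.overlaps(xb[1], xb[2], ca[, 1], ca[, 2]))) next
        la <- ia[k - 1L, ]; ra <- ia[k, ]
        lb <- ib[m - 1L, ]; rb <- ib[m, ]
        if (la[1] != lb[1] || ra[2] != rb[2]) next
        fa <- c(which(key(ua) == paste(la[1], la[2])),
                which(key(ua) == paste(ra[1], ra[2])))
        fb <- c(which(key(ub) == paste(lb[1], lb[2])),
                which(key(ub) == paste(rb[1], rb[2])))
        if (length(fa) < 2L || length(fb) < 2L) next
        if (any(used_a[fa]) || any(used_b[fb])) next
        # inclusion = isoform carrying the 5' exon in transcript orientation
        a_is_5prime <- if (plus) xa[1] < xb[1] else xa[1] > xb[1]
        inc <- if (a_is_5prime) ida else idb
        exc <- if (a_is_5prime) idb else ida
        add("MXE", min(xa[1], xb[1]), max(xa[2], xb[2]), inc, exc,
            la[1], ra[2])
        used_a[fa] <- TRUE; used_b[fb] <- TRUE
      }
    }
  }

  # --- A5SS / A3SS: unique introns sharing exactly one boundary
  for (i in seq_len(nrow(ua))) {
    if (used_a[i]) next
    for (j in seq_len(nrow(ub))) {
      if (used_b[j]) next
      sa <- ua[i, 1]; ea <- ua[i, 2]; sb <- ub[j, 1]; eb <- ub[j, 2]
      share_start <- sa == sb && ea != eb
      share_end <- ea == eb && sa != sb
      if (!share_start && !share_end) next
      if (share_start) {
        # differing right boundary (genomic): acceptor on +, donor on -
        type <- if (plus) "A3SS" else "A5SS"
        vs <- min(ea, eb); ve <- max(ea, eb)
        fl <- sa; fr <- max(ea, eb)
      } else {
        type <- if (plus) "A5SS" else "A3SS"
        vs <- min(sa, sb); ve <- max(sa, sb)
        fl <- min(sa, sb); fr <- ea
      }
      # inclusion = shorter intron (more exonic sequence)
      inc <- if ((ea - sa) < (eb - sb)) ida else idb
      exc <- if ((ea - sa) < (eb - sb)) idb else ida
      add(type, vs, ve, inc, exc, fl, fr)
      used_a[i] <- TRUE; used_b[j] <- TRUE
      break
    }
  }

  # --- complex: leftover structural differences, one event per contiguous
  #     difference region
  left_a <- ua[!used_a, , drop = FALSE]
  left_b <- ub[!used_b, , drop = FALSE]
  if (nrow(left_a) || nrow(left_b)) {
    regs <- merge_intervals(rbind(left_a, left_b))
    for (r in seq_len(nrow(regs))) {
      add("complex", regs[r, 1], regs[r, 2], ida, idb)
    }
  }

  out <- dplyr::bind_rows(ev)
  out[order(out$var_start, out$var_end, out$event_type), , drop = FALSE]
}

merge_intervals <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

#' Enumerate the merged AS events of a multi-isoform locus
#'
#' Runs [classify_pair()] over all unordered isoform pairs and merges
#' identical events (same type, variable region and flanks), unioning their
#' inclusion and exclusion isoform sets.
#'
#' @param tx `transcript_models` tibble holding the locus members (or a
#'   larger table plus `locus_id` to select).
#' @param locus_id optional locus to select from `tx`.
#' @return merged event tibble with an `event_id` column.
#' @export
enumerate_locus_events <- function(tx, locus_id = NULL) {
  if (!is.null(locus_id)) tx <- tx[tx$locus_id == locus_id, , drop = FALSE]
  n <- nrow(tx)
  if (n < 2L) return(cbind(empty_events(), tibble::tibble(event_id = character(0))))
  evs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      e <- classify_pair(tx[i, , drop = FALSE], tx[j, , drop = FALSE])
      if (nrow(e)) evs[[length(evs) + 1L]] <- e
    }
  }
  ev <- dplyr::bind_rows(evs)
  if (!nrow(ev)) return(cbind(empty_events(), tibble::tibble(event_id = character(0))))
  gkey <- paste(ev$event_type, ev$chrom, ev$strand, ev$var_start, ev$var_end,
                ev$flank_left, ev$flank_right)
  merged <- lapply(split(seq_len(nrow(ev)), gkey), function(i) {
    r <- ev[i[1L], , drop = FALSE]
    r$inclusion <- list(sort(unique(unlist(ev$inclusion[i]))))
    r$exclusion <- list(sort(unique(setdiff(unlist(ev$exclusion[i]),
                                            unlist(ev$inclusion[i])))))
    r
  })
  out <- dplyr::bind_rows(merged)
  out <- out[order(out$var_start, out$var_end, out$event_type), , drop = FALSE]
  out <- out[lengths(out$exclusion) > 0L, , drop = FALSE]
  out$event_id <- sprintf("%s:%s:%d-%d:%s", out$locus_id, out$event_type,
                          out$var_start, out$var_end, out$strand)
  out
}

#' Enumerate merged AS events for every locus of an annotation
#' @param tx `transcript_models` tibble with locus assignments.
#' @return merged event tibble over all loci.
#' @export
enumerate_all_events <- function(tx) {
  per <- lapply(split(seq_len(nrow(tx)), tx$locus_id), function(i) {
    enumerate_locus_events(tx[i, , drop = FALSE])
  })
  dplyr::bind_rows(per)
}

#' Fraction of a junction set supported by an external junction set
#'
#' Junction equality is exact on (chrom, strand, intron start, intron end).
#'
#' @param isoform_junctions tibble (chrom, strand, intron_start, intron_end).
#' @param support_set tibble in the same format (e.g. short-read junctions).
#' @return supported fraction in \[0, 1\].
#' @export
junction_support_fraction <- function(isoform_junctions, support_set) {
  if (!nrow(isoform_junctions)) stop("empty isoform junction set")
  jk <- function(j) paste(j$chrom, j$strand, j$intron_start, j$intron_end)
  mean(jk(isoform_junctions) %in% jk(support_set))
}

#' Write events as TSV
#' @param events event tibble from [enumerate_locus_events()].
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_events_tsv <- function(events, path) {
  flat <- data.frame(
    event_id = events$event_id, locus_id = events$locus_id,
    event_type = events$event_type, chrom = events$chrom,
    strand = events$strand, var_start = events$var_start,
    var_end = events$var_end,
    inclusion = vapply(events$inclusion, paste, character(1), collapse = ","),
    exclusion = vapply(events$exclusion, paste, character(1), collapse = ",")
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a junction set as 6-column BED (intron coordinates)
#' @param junctions tibble (chrom, strand, intron_start, intron_end).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  bed <- data.frame(
    chrom = junctions$chrom,
    start = junctions$intron_start,
    end = junctions$intron_end,
    name = sprintf("JUNC%05d", seq_len(nrow(junctions))),
    score = 0L,
    strand = junctions$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a junction BED written by [write_junction_bed()]
#' @param path BED path.
#' @return junction tibble (chrom, strand, intron_start, intron_end).
#' @export
read_junction_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  tibble::tibble(
    chrom = as.character(bed[[1]]), strand = as.character(bed[[6]]),
    intron_start = as.integer(bed[[2]]), intron_end = as.integer(bed[[3]])
  )
}
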