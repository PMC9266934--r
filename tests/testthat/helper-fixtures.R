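# fixture builders and tiny independent oracles shared across test files

# shorthand transcript table: exon lists given as c(s1,e1, s2,e2, ...)
mk_tx <- function(ids, exon_vecs, strand = "+", chrom = "chr1",
                  locus = "L1", biotype = "coding",
                  cds_start = NA_integer_, cds_end = NA_integer_) {
  transcript_models(
    transcript_id = ids, locus_id = locus, chrom = chrom, strand = strand,
    exons = lapply(exon_vecs, function(v) matrix(v, ncol = 2, byrow = TRUE)),
    cds_start = cds_start, cds_end = cds_end, biotype = biotype
  )
}

# small expression matrix over an explicit design
mk_expr <- function(values, design) {
  expression_matrix(values, design)
}

# design with 1 condition pair, arbitrary times/reps
mk_design <- function(times = c(1, 15), reps = 3) {
  experimental_design(time_points = times, replicates = reps)
}

# independent union-find over all transcript pairs (locus-grouping oracle)
brute_force_loci <- function(tx, min_overlap = 1L) {
  n <- nrow(tx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  exonic_ov <- function(i, j) {
    if (tx$chrom[i] != tx$chrom[j] || tx$strand[i] != tx$strand[j]) return(0L)
    a <- tx$exons[[i]]; b <- tx$exons[[j]]
    ov <- 0L
    for (r in seq_len(nrow(a))) {
      ov <- max(ov, max(0L, pmin(a[r, 2], b[, 2]) - pmax(a[r, 1], b[, 1])))
    }
    ov
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (exonic_ov(i, j) >= min_overlap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# adjusted Rand index between two label vectors
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# naive 3-frame ORF scan (oracle for find_orf): all ATG..stop, longest,
# tie towards smallest start
brute_force_orf <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  best <- NULL
  for (st in seq_len(max(0, n - 5))) {
    if (!(ch[st] == "A" && ch[st + 1] == "T" && ch[st + 2] == "G")) next
    pos <- st + 3
    while (pos + 2 <= n) {
      cod <- paste0(ch[pos], ch[pos + 1], ch[pos + 2])
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- pos + 3 - st
        if (is.null(best) || len > best$len ||
            (len == best$len && st < best$start)) {
          best <- list(start = st, len = len)
        }
        break
      }
      pos <- pos + 3
    }
  }
  if (is.null(best)) return(NULL)
  list(orf_start = best$start - 1L, orf_end = best$start - 1L + best$len,
       cds_length = best$len)
}

# random DNA sequence
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
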