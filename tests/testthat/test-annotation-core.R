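test_that("GTF coordinates convert to 0-based half-open on read", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0('chr1\ttest\texon\t101\t200\t.\t+\t.\t',
                    'gene_id "G1"; transcript_id "T1";'), f)
  tx <- read_gtf(f)
  expect_equal(tx$exons[[1]][1, "start"], c(start = 100L))
  expect_equal(tx$exons[[1]][1, "end"], c(end = 200L))
})

test_that("write/read round trip preserves models exactly, GTF and GFF3", {
  set.seed(5)
  cfg <- simulation_config(n_loci = 40, n_planted_nmd = 3, seed = 5)
  tx <- generate_annotation(cfg)$transcripts
  for (fmt in c("gtf", "gff3")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_gtf(tx, f, format = fmt)
    back <- read_gtf(f)
    back <- back[match(tx$transcript_id, back$transcript_id), ]
    expect_identical(back$transcript_id, tx$transcript_id)
    expect_identical(unname(back$exons), unname(tx$exons))
    expect_identical(back$strand, tx$strand)
    expect_identical(back$locus_id, tx$locus_id)
    expect_identical(back$biotype, tx$biotype)
    expect_identical(back$cds_start, tx$cds_start)
    expect_identical(back$cds_end, tx$cds_end)
  }
})

test_that("transcript validation rejects malformed models", {
  expect_error(mk_tx("T1", list(c(100, 200, 150, 300))), "overlapping")
  expect_error(mk_tx("T1", list(c(100, 100))), "zero-width")
  expect_error(
    transcript_models("T1", "L1", "chr1", "?", list(cbind(0, 100))),
    "strand"
  )
  expect_error(mk_tx("T1", list(c(100, 200)), cds_start = 150, cds_end = 300),
               "CDS")
})

test_that("locus grouping partitions transcripts by chained exonic overlap", {
  # disjoint spans -> 2 loci
  tx <- mk_tx(c("A", "B"), list(c(0, 100), c(1000, 1100)))
  expect_equal(nrow(group_into_loci(tx)), 2L)
  # A~B, B~C, A disjoint C -> one locus by transitivity
  tx <- mk_tx(c("A", "B", "C"),
              list(c(0, 100), c(50, 200), c(150, 300)))
  loci <- group_into_loci(tx)
  expect_equal(nrow(loci), 1L)
  expect_setequal(loci$transcript_ids[[1]], c("A", "B", "C"))
  # strand separation
  tx2 <- mk_tx(c("P", "M"), list(c(0, 100), c(0, 100)),
               strand = c("+", "-"))
  expect_equal(nrow(group_into_loci(tx2)), 2L)
  expect_equal(nrow(group_into_loci(tx2, require_same_strand = FALSE)), 1L)
})

test_that("locus grouping matches a brute-force union-find oracle", {
  set.seed(99)
  n <- 100
  starts <- sample(0:20000, n)
  tx <- transcript_models(
    transcript_id = sprintf("T%03d", seq_len(n)),
    locus_id = "x", chrom = "chr1",
    strand = sample(c("+", "-"), n, TRUE),
    exons = lapply(starts, function(s) {
      k <- sample(1:3, 1)
      e <- random_exon_starts <- s + cumsum(c(0, sample(150:400, k * 2 - 1, TRUE)))
      m <- matrix(e[seq_len(2 * k)], ncol = 2, byrow = TRUE)
      m
    })
  )
  loci <- group_into_loci(tx)
  got <- rep(NA_integer_, n)
  for (i in seq_len(nrow(loci))) {
    got[match(loci$transcript_ids[[i]], tx$transcript_id)] <- i
  }
  oracle <- brute_force_loci(tx)
  # same partition: label vectors agree up to relabelling
  expect_equal(adjusted_rand_index(got, oracle), 1)
  expect_true(all(table(tx$transcript_id[!is.na(got)]) == 1))
})

test_that("isoform and exon summary statistics follow their definitions", {
  tx <- mk_tx(c("A1", "B1", "B2", "C1", "C2"),
              list(c(0, 100), c(1000, 1100), c(1000, 1100, 1200, 1300),
                   c(5000, 5100), c(5050, 5200)),
              locus = c("A", "B", "B", "C", "C"))
  h <- isoforms_per_locus_histogram(tx)
  expect_equal(sum(h$fraction), 1)
  expect_equal(attr(h, "multi_isoform_fraction"), 2 / 3)
  st <- exons_per_isoform_stats(tx)
  expect_equal(st$mean, 6 / 5)
  expect_equal(st$single_exon_fraction, 4 / 5)
  expect_error(exons_per_isoform_stats(tx[0, ]), "empty")
  # generator hits its configured exon mean within 5% at n = 2000
  cfg <- simulation_config(n_loci = 700, exons_per_isoform_mean = 8, seed = 2)
  g <- generate_annotation(cfg)$transcripts
  expect_gt(nrow(g), 1000)
  expect_lt(abs(exons_per_isoform_stats(g)$mean - 8) / 8, 0.05)
})

test_that("reference classification follows the structural category rules", {
  ref <- mk_tx(c("R1", "R2"),
               list(c(0, 100, 200, 300, 400, 500, 600, 700),
                    c(2000, 2100, 2200, 2300)),
               locus = c("G1", "G2"))
  # identical chain
  iso <- mk_tx("q", list(c(0, 100, 200, 300, 400, 500, 600, 700)))
  expect_equal(classify_vs_reference(iso, ref), "full_splice_match")
  # contiguous sub-chain (drop first exon)
  iso <- mk_tx("q", list(c(200, 300, 400, 500, 600, 700)))
  expect_equal(classify_vs_reference(iso, ref), "incomplete_splice_match")
  # all junctions known, new combination (skip one exon of R1)
  iso <- mk_tx("q", list(c(0, 100, 200, 300, 600, 700)))
  expect_equal(classify_vs_reference(iso, ref), "novel_not_in_catalog")
  # novel junction at known locus (shifted donor)
  iso <- mk_tx("q", list(c(0, 90, 200, 300, 400, 500, 600, 700)))
  expect_equal(classify_vs_reference(iso, ref), "novel_not_in_catalog")
  # all junctions known but the combination (skipping a middle junction)
  # is not a contiguous sub-chain of any reference transcript
  iso <- mk_tx("q", list(c(50, 100, 200, 500, 600, 650)))
  expect_equal(classify_vs_reference(iso, ref), "novel_in_catalog")
  # far away with no overlap
  iso <- mk_tx("q", list(c(50000, 50100)))
  expect_equal(classify_vs_reference(iso, ref), "intergenic")
  # opposite strand overlap only
  iso <- mk_tx("q", list(c(10, 650)), strand = "-")
  expect_equal(classify_vs_reference(iso, ref), "antisense")
  # mono-exon reciprocal-overlap match
  ref2 <- mk_tx("R3", list(c(0, 1000)))
  iso <- mk_tx("q", list(c(100, 900)))
  expect_equal(classify_vs_reference(iso, ref2), "full_splice_match")
})

test_that("reference classification is invariant to reference order and
           labels constructed perturbations correctly", {
  set.seed(31)
  cfg <- simulation_config(n_loci = 60, seed = 31)
  ref <- generate_annotation(cfg)$transcripts
  # perturb only isoforms of mono-isoform loci: sibling isoforms of a
  # multi-isoform locus can legitimately absorb a perturbed chain into a
  # different (correct) category
  solo <- names(which(table(ref$locus_id) == 1))
  multi <- ref[ref$locus_id %in% solo &
                 vapply(ref$exons, nrow, integer(1)) >= 4, ]
  cases <- 0
  for (i in seq_len(min(50, nrow(multi)))) {
    r <- multi[i, , drop = FALSE]
    # identical copy
    expect_equal(classify_vs_reference(r, ref), "full_splice_match")
    # drop first exon -> contiguous sub-chain
    sub <- r
    sub$exons[[1]] <- sub$exons[[1]][-1, , drop = FALSE]
    expect_equal(classify_vs_reference(sub, ref), "incomplete_splice_match")
    # shift an internal donor by 3 -> novel junction at a known locus
    shifted <- r
    ex <- shifted$exons[[1]]
    ex[2, 2] <- ex[2, 2] - 3L
    shifted$exons[[1]] <- ex
    expect_equal(classify_vs_reference(shifted, ref), "novel_not_in_catalog")
    # shuffled reference order must not change any label
    ref_shuf <- ref[sample(nrow(ref)), ]
    expect_equal(classify_vs_reference(shifted, ref_shuf),
                 "novel_not_in_catalog")
    cases <- cases + 4
  }
  expect_gte(cases, 60)
})

test_that("shared-junction fraction is 1 for copies of the reference", {
  cfg <- simulation_config(n_loci = 10, seed = 8)
  ref <- generate_annotation(cfg)$transcripts
  multi <- ref[vapply(ref$exons, nrow, integer(1)) >= 2, ]
  expect_equal(shared_junction_fraction(multi, ref), 1.0)
})

test_that("library summary totals recompute from the per-library rows", {
  ls <- read_library_summary()
  expect_equal(unname(ls$totals), unname(ls$printed_totals))
})
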