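test_that("lncRNA candidate filtering applies the strict 100 aa ORF rule", {
  tx <- mk_tx(c("T1", "T2", "T3", "T4"),
              list(c(0, 600), c(1000, 1600), c(2000, 2600), c(3000, 3600)),
              locus = c("A", "B", "C", "D"), biotype = "lncRNA")
  labels <- tibble::tibble(
    transcript_id = c("T1", "T2", "T3", "T4"),
    label = c("noncoding", "noncoding", "noncoding", "coding"),
    orf_aa = c(150, 100, 0, 10)
  )
  got <- filter_lnc_candidates(tx, labels)
  expect_setequal(got, c("T2", "T3"))  # 150 aa removed; 100 aa kept (strict >)
  # exclusion list removes further candidates
  expect_equal(filter_lnc_candidates(tx, labels, exclusion_list = "T3"), "T2")
  # ORF length from sequence when the label table lacks it
  labels2 <- labels[, c("transcript_id", "label")]
  seqs <- c(T1 = paste0("AAA", "ATG", strrep("GGG", 120), "TAA"),
            T2 = strrep("C", 50), T3 = strrep("C", 50))
  got2 <- filter_lnc_candidates(tx, labels2, sequences = seqs)
  expect_setequal(got2, c("T2", "T3"))   # T1's 121-codon ORF is > 100 aa
  expect_error(filter_lnc_candidates(tx, labels2), "lacks both")
})

pc_fixture <- function(offset = 0L) {
  mk_tx(c("PC1", "PC2"),
        list(c(10000, 10500, 11000, 11500) + offset,
             c(40000, 40800) + offset),
        strand = c("+", "+"), locus = c("G1", "G2"))
}

test_that("positional classification follows the priority and distance
           rules", {
  pc <- pc_fixture()
  # antisense exon-exon overlap
  lnc <- mk_tx("N1", list(c(10200, 10700)), strand = "-", biotype = "lncRNA")
  got <- classify_lnc(lnc, pc)
  expect_equal(got$category, "antisense")
  expect_equal(got$subcategory, "lncNAT_exonic")
  expect_equal(got$partner_pc_transcript, "PC1")
  # antisense but fully intronic
  lnc <- mk_tx("N2", list(c(10600, 10900)), strand = "-", biotype = "lncRNA")
  got <- classify_lnc(lnc, pc)
  expect_equal(got$category, "antisense")
  expect_equal(got$subcategory, "lncNAT_intronic")
  # sense intronic
  lnc <- mk_tx("N3", list(c(10600, 10900)), strand = "+", biotype = "lncRNA")
  got <- classify_lnc(lnc, pc)
  expect_equal(got$category, "sense_overlapping")
  expect_equal(got$subcategory, "sense_intronic")
  # > 2 kb from the nearest PC transcript: lincRNA
  lnc <- mk_tx("N4", list(c(16500, 17000)), strand = "+", biotype = "lncRNA")
  got <- classify_lnc(lnc, pc)
  expect_equal(got$category, "intergenic")
  expect_equal(got$subcategory, "lincRNA_distal")
  expect_equal(got$distance_to_partner, 5000L)
  # 1500 nt upstream of PC1 (same strand, no overlap)
  lnc <- mk_tx("N5", list(c(8000, 8500)), strand = "+", biotype = "lncRNA")
  got <- classify_lnc(lnc, pc)
  expect_equal(got$category, "proximal")
  expect_equal(got$subcategory, "intergenic_proximal_upstream")
  expect_equal(got$distance_to_partner, 1500L)
  # same position, opposite strand: head-to-head promoter arrangement
  lnc <- mk_tx("N6", list(c(8000, 8500)), strand = "-", biotype = "lncRNA")
  got <- classify_lnc(lnc, pc)
  expect_equal(got$subcategory, "bidirectional_promoter")
  # 1200 nt downstream of PC1
  lnc <- mk_tx("N7", list(c(12700, 13000)), strand = "+", biotype = "lncRNA")
  got <- classify_lnc(lnc, pc)
  expect_equal(got$subcategory, "intergenic_proximal_downstream")
})

test_that("classification is total and translation-invariant", {
  cfg <- simulation_config(n_loci = 30, n_lncnat = 4, n_lincrna = 4,
                           seed = 27)
  ann <- generate_annotation(cfg)
  tx <- ann$transcripts
  lnc <- tx[tx$biotype == "lncRNA", ]
  pc <- tx[tx$biotype == "coding", ]
  cls <- classify_all_lnc(lnc, pc)
  expect_equal(nrow(cls), nrow(lnc))
  expect_false(any(is.na(cls$category)))
  expect_false(any(is.na(cls$subcategory)))
  # planted placements are recovered exactly
  pl <- ann$truth$planted_lnc_pairs
  m <- match(pl$lnc_id, cls$transcript_id)
  expect_equal(cls$category[m], pl$category)
  expect_equal(cls$subcategory[m], pl$subcategory)
  # shifting all coordinates by a constant changes nothing
  shift <- 13337L
  lnc2 <- lnc; pc2 <- pc
  lnc2$exons <- lapply(lnc2$exons, function(m) m + shift)
  pc2$exons <- lapply(pc2$exons, function(m) m + shift)
  pc2$cds_start <- pc2$cds_start + shift; pc2$cds_end <- pc2$cds_end + shift
  cls2 <- classify_all_lnc(lnc2, pc2)
  expect_equal(cls2$category, cls$category)
  expect_equal(cls2$subcategory, cls$subcategory)
  expect_equal(cls2$distance_to_partner, cls$distance_to_partner)
})

test_that("feature comparison separates planted exon-count shifts", {
  d <- experimental_design(time_points = 1, replicates = 1)
  set.seed(5)
  n <- 200
  ids <- c(paste0("LNC", 1:n), paste0("M", 1:n))
  tx <- transcript_models(
    transcript_id = ids, locus_id = ids, chrom = "chr1", strand = "+",
    exons = c(
      lapply(seq_len(n), function(i) cbind(i * 10000, i * 10000 + 500)),
      lapply(seq_len(n), function(i) {
        s <- 10^7 + i * 10000 + seq(0, 900, by = 100)
        cbind(s, s + 50)
      })
    ),
    biotype = rep(c("lncRNA", "coding"), each = n)
  )
  vals <- matrix(stats::rexp(2 * n * 2), nrow = 2 * n,
                 dimnames = list(ids, d$sample_id))
  expr <- expression_matrix(vals, d)
  got <- lnc_feature_comparison(paste0("LNC", 1:n), paste0("M", 1:n), tx, expr)
  p_exon <- got$tests$p_value[got$tests$feature == "exon_count"]
  expect_lt(p_exon, 1e-10)
  expect_error(lnc_feature_comparison(character(0), paste0("M", 1:n), tx,
                                      expr), "empty")
})

test_that("planted lnc/PC correlation structure is recovered", {
  cfg <- simulation_config(n_loci = 40, n_lncnat = 8, n_lincrna = 8,
                           lnc_pc_correlation = 0.9, seed = 41)
  ann <- generate_annotation(cfg)
  expr <- generate_expression(ann$transcripts, ann$truth, cfg)
  tx <- ann$transcripts
  cls <- classify_all_lnc(tx[tx$biotype == "lncRNA", ],
                          tx[tx$biotype == "coding", ])
  corr <- lnc_pc_correlation(cls, expr)
  expect_gte(corr$category_medians[["antisense"]], 0.6)
  expect_lte(abs(corr$category_medians[["intergenic"]]), 0.35)
  # identical partner profile: rho 1
  d <- experimental_design(time_points = c(1, 4, 6), replicates = 1)
  prof <- c(1, 5, 2, 4, 3, 6)   # one value per design sample
  vals <- rbind(LNC = prof, PC = prof)
  colnames(vals) <- d$sample_id
  cls1 <- tibble::tibble(transcript_id = "LNC", category = "antisense",
                         subcategory = "lncNAT_exonic",
                         partner_pc_transcript = "PC",
                         distance_to_partner = 0L)
  got <- lnc_pc_correlation(cls1, expression_matrix(vals, d))
  expect_equal(got$pairs$rho, 1)
})
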