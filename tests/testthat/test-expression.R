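test_that("gene expression is the exact sum of member isoforms", {
  d <- experimental_design(time_points = c(1, 15), replicates = 2)
  set.seed(3)
  vals <- matrix(stats::rexp(4 * nrow(d)), nrow = 4,
                 dimnames = list(c("A.1", "A.2", "B.1", "C.1"), d$sample_id))
  expr <- expression_matrix(vals, d)
  tx <- mk_tx(c("A.1", "A.2", "B.1", "C.1"),
              list(c(0, 100), c(0, 100), c(1000, 1100), c(2000, 2100)),
              locus = c("A", "A", "B", "C"))
  g <- gene_expression_from_isoforms(expr, tx)
  expect_equal(g$values["A", ], vals["A.1", ] + vals["A.2", ])
  expect_equal(g$values["B", ], vals["B.1", ])
  expect_equal(colSums(g$values), colSums(vals))
  # orphan isoform errors
  rownames(vals)[4] <- "ORPHAN"
  expect_error(gene_expression_from_isoforms(expression_matrix(vals, d), tx),
               "without locus")
})

test_that("expression thresholds are strict inequalities", {
  d <- experimental_design(time_points = 1, replicates = 1)
  gene_vals <- matrix(c(0.1, 0.1, 0.11, 0.05, 0, 0), nrow = 3, byrow = TRUE,
                      dimnames = list(c("G1", "G2", "G3"), d$sample_id))
  iso_vals <- matrix(c(0.01, 0.01, 0.02, 0, 0, 0), nrow = 3, byrow = TRUE,
                     dimnames = list(c("T1", "T2", "T3"), d$sample_id))
  got <- apply_expression_thresholds(expression_matrix(gene_vals, d),
                                     expression_matrix(iso_vals, d))
  expect_equal(got$expressed_genes, "G2")     # 0.1 exactly is not expressed
  expect_equal(got$expressed_isoforms, "T2")  # one sample above suffices
})

test_that("the DE stand-in is empty under identical means and finds planted
           fold changes", {
  d <- experimental_design(time_points = 15, replicates = 3)
  vals <- matrix(rep(c(4, 4, 4, 4, 4, 4), 5), nrow = 5, byrow = TRUE,
                 dimnames = list(paste0("G", 1:5), d$sample_id))
  de <- call_de(expression_matrix(vals, d), 15)
  expect_false(any(de$significant))
  # planted 8-fold change with low noise
  set.seed(6)
  inoc <- grepl("^inoculated", d$sample_id)
  vals2 <- matrix(2^(3 + stats::rnorm(5 * 6, sd = 0.1)), nrow = 5,
                  dimnames = list(paste0("G", 1:5), d$sample_id))
  vals2[1, inoc] <- vals2[1, inoc] * 8
  de2 <- call_de(expression_matrix(vals2, d), 15)
  expect_true(de2$significant[de2$feature_id == "G1"])
  d1 <- experimental_design(time_points = 15, replicates = 1)
  v1 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), d1$sample_id))
  expect_error(call_de(expression_matrix(v1, d1), 15), "replicates")
})

test_that("DE/DS sets are disjoint, complete, and seed-reproducible", {
  sets <- build_de_ds_sets(de_genes = c("A", "B", "C"),
                           ds_genes = c("B", "C", "D"),
                           expressed_genes = LETTERS[1:10],
                           n_random = 5, seed = 42)
  expect_equal(sets$de_no_ds, "A")
  expect_equal(sets$no_de_ds, "D")
  expect_setequal(sets$de_ds, c("B", "C"))
  expect_length(intersect(sets$de_no_ds, sets$no_de_ds), 0)
  sets2 <- build_de_ds_sets(c("A", "B", "C"), c("B", "C", "D"),
                            LETTERS[1:10], n_random = 5, seed = 42)
  expect_identical(sets$random_control, sets2$random_control)
  # disjoint inputs / equal inputs edge cases
  s3 <- build_de_ds_sets("A", "B", LETTERS[1:4], seed = 1)
  expect_length(s3$de_ds, 0)
  s4 <- build_de_ds_sets(c("A", "B"), c("A", "B"), LETTERS[1:4], seed = 1)
  expect_length(s4$de_no_ds, 0)
  expect_length(s4$no_de_ds, 0)
})

test_that("gene-transcript Spearman correlation behaves at the extremes", {
  d <- experimental_design(time_points = c(1, 4, 6, 8, 10), replicates = 1)
  n <- nrow(d)
  set.seed(11)
  prof <- stats::rexp(n) + seq_len(n)
  vals <- rbind("A.1" = prof, "B.1" = prof, "B.2" = rev(prof) * 2)
  colnames(vals) <- d$sample_id
  tx <- mk_tx(c("A.1", "B.1", "B.2"),
              list(c(0, 100), c(1000, 1100), c(1000, 1100)),
              locus = c("A", "B", "B"))
  expr <- expression_matrix(vals, d)
  g <- gene_expression_from_isoforms(expr, tx)
  # single-isoform gene: rho forced to 1 by the sum construction
  got_a <- gene_transcript_scc("A", g, expr, tx)
  expect_equal(got_a$pairs$rho, 1)
  expect_equal(got_a$median_rho, 1)
  # a transcript identical to an anti-monotone sibling
  got_b <- gene_transcript_scc("B", g, expr, tx)
  expect_equal(nrow(got_b$pairs), 2)
  # monotone-transform invariance of Spearman
  expr_t <- expression_matrix(vals^3, d)
  g_t <- gene_expression_from_isoforms(expr_t, tx)
  got_a_t <- gene_transcript_scc("A", g_t, expr_t, tx)
  expect_equal(got_a_t$pairs$rho, got_a$pairs$rho)
  # constant profiles are excluded and counted
  vals_c <- rbind("A.1" = rep(1, n)); colnames(vals_c) <- d$sample_id
  expr_c <- expression_matrix(vals_c, d)
  g_c <- gene_expression_from_isoforms(expr_c, tx[1, ])
  got_c <- gene_transcript_scc("A", g_c, expr_c, tx[1, ])
  expect_equal(got_c$n_excluded_constant, 1L)
})

test_that("DS/DE count correlation reproduces exact and null cases", {
  ds <- c(10, 20, 30, 40, 50)
  r <- dsg_deg_count_correlation(ds, 2 * ds)
  expect_equal(r$r, 1.0)
  r2 <- dsg_deg_count_correlation(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r2$r, -1.0)
  expect_error(dsg_deg_count_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  # independent vectors: mean correlation near zero
  set.seed(21)
  rs <- replicate(1000, dsg_deg_count_correlation(stats::rnorm(9),
                                                  stats::rnorm(9))$r)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("null DE calibration stays near the nominal level", {
  d <- experimental_design(time_points = 15, replicates = 3)
  set.seed(17)
  vals <- matrix(2^(3 + stats::rnorm(2000 * 6, sd = 0.3)), nrow = 2000,
                 dimnames = list(paste0("G", 1:2000), d$sample_id))
  de <- call_de(expression_matrix(vals, d), 15)
  frac <- mean(de$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})
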