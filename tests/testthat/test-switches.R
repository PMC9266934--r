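# two-isoform locus expression over the full design where majors can be
# scripted per (condition, time) cell: ratio_a gives isoform A's usage
mk_two_iso_expr <- function(ratio_a, design, total = 10) {
  cells <- unique(paste(design$condition, design$time, sep = "_"))
  stopifnot(length(ratio_a) == length(cells))
  names(ratio_a) <- cells
  cell_of <- paste(design$condition, design$time, sep = "_")
  vals <- rbind(
    "L.1" = total * ratio_a[cell_of],
    "L.2" = total * (1 - ratio_a[cell_of])
  )
  colnames(vals) <- design$sample_id
  expression_matrix(vals, design)
}

two_iso_tx <- function() {
  mk_tx(c("L.1", "L.2"), list(c(0, 100, 200, 300), c(0, 300)), locus = "L")
}

test_that("major-isoform calls apply the strict >50% dominance rule", {
  d <- experimental_design(time_points = 1, replicates = 1)
  vals <- matrix(c(6, 6, 3, 3, 1, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("L.1", "L.2", "L.3"), d$sample_id))
  tx <- mk_tx(c("L.1", "L.2", "L.3"),
              list(c(0, 100), c(0, 100), c(0, 100)), locus = "L")
  calls <- call_major_isoforms(expression_matrix(vals, d), tx)
  expect_equal(calls$major_isoform, rep("L.1", 2))
  expect_equal(calls$ratio, rep(0.6, 2))
  # 50/50: no major (0.5 is not > 0.5)
  vals2 <- matrix(c(5, 5, 5, 5), nrow = 2, byrow = TRUE,
                  dimnames = list(c("L.1", "L.2"), d$sample_id))
  calls2 <- call_major_isoforms(expression_matrix(vals2, d), two_iso_tx())
  expect_true(all(is.na(calls2$major_isoform)))
  expect_equal(calls2$ratio, rep(0.5, 2))
  # single expressed isoform: ratio 1
  vals3 <- matrix(c(5, 5, 0, 0), nrow = 2, byrow = TRUE,
                  dimnames = list(c("L.1", "L.2"), d$sample_id))
  calls3 <- call_major_isoforms(expression_matrix(vals3, d), two_iso_tx())
  expect_equal(calls3$major_isoform, rep("L.1", 2))
  expect_equal(calls3$ratio, rep(1, 2))
})

test_that("switch detection applies the ratio-change cutoff", {
  d <- experimental_design(time_points = 15, replicates = 1)
  # A major 0.8 inoculated, B major 0.7 (A at 0.2) uninoculated: change 0.6
  expr <- mk_two_iso_expr(c(0.8, 0.2), d)
  sw <- detect_switches(call_major_isoforms(expr, two_iso_tx()))
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$ratio_change, 0.6)
  expect_setequal(c(sw$former, sw$latter), c("L.1", "L.2"))
  # 0.55 vs 0.45: candidate change 0.10 <= 0.3 -> discarded
  expr2 <- mk_two_iso_expr(c(0.55, 0.45), d)
  sw2 <- detect_switches(call_major_isoforms(expr2, two_iso_tx()))
  expect_equal(nrow(sw2), 0L)
  # no switch when the same isoform dominates everywhere
  expr3 <- mk_two_iso_expr(c(0.8, 0.75), d)
  expect_equal(nrow(detect_switches(call_major_isoforms(expr3, two_iso_tx()))),
               0L)
})

test_that("switch categorisation separates stage-specific, continuous and
           irreversible patterns", {
  d <- experimental_design()  # 9 time points, 3 reps
  tps <- sort(unique(d$time))
  cells <- unique(paste(d$condition, d$time, sep = "_"))
  ratio <- function(inoc_a, uninoc_a) {
    r <- c(inoc_a, uninoc_a)
    names(r) <- c(paste("inoculated", tps, sep = "_"),
                  paste("uninoculated", tps, sep = "_"))
    r[cells]
  }
  run <- function(ratio_a) {
    expr <- mk_two_iso_expr(ratio_a, d)
    sw <- detect_switches(call_major_isoforms(expr, two_iso_tx()))
    categorize_switches(sw, d)
  }
  # switch only at 20 dpi -> stage_specific
  one <- run(ratio(ifelse(tps == 20, 0.2, 0.8), rep(0.8, 9)))
  expect_equal(one$category, "stage_specific")
  expect_equal(one$switch_times[[1]], 20)
  expect_equal(one$former, "L.1")
  expect_equal(one$latter, "L.2")
  # inoculated flips at 15 dpi and stays; uninoculated keeps the former
  irr <- run(ratio(ifelse(tps >= 15, 0.2, 0.8), rep(0.8, 9)))
  expect_equal(irr$category, "irreversible_inoculated")
  expect_equal(irr$switch_times[[1]], c(15, 20, 25, 30))
  # uninoculated flips instead: continuous but not irreversible
  cont <- run(ratio(rep(0.8, 9), ifelse(tps >= 20, 0.2, 0.8)))
  expect_equal(cont$category, "continuous")
  # switch at 15 and 25 but not 20/30: two stage-specific records
  scat <- run(ratio(ifelse(tps %in% c(15, 25), 0.2, 0.8), rep(0.8, 9)))
  expect_equal(nrow(scat), 2L)
  expect_true(all(scat$category == "stage_specific"))
  expect_equal(sort(unlist(scat$switch_times)), c(15, 25))
})

test_that("planted switches are recovered with their categories and no
           spurious loci appear at zero noise", {
  cfg <- simulation_config(n_loci = 40, n_planted_switches = 9,
                           noise_sd_log2 = 0, seed = 19)
  ann <- generate_annotation(cfg)
  expr <- generate_expression(ann$transcripts, ann$truth, cfg)
  sw <- detect_switches(call_major_isoforms(expr, ann$transcripts))
  sw <- categorize_switches(sw, expr$design)
  tr <- ann$truth$planted_switches
  expect_setequal(unique(sw$locus_id), tr$locus_id)
  m <- match(tr$locus_id, sw$locus_id)
  expect_equal(sw$former[m], tr$former)
  expect_equal(sw$latter[m], tr$latter)
  expect_equal(sw$category[m], tr$category)
})

test_that("switch detection is invariant to isoform relabelling", {
  cfg <- simulation_config(n_loci = 20, n_planted_switches = 4,
                           noise_sd_log2 = 0.2, seed = 23)
  ann <- generate_annotation(cfg)
  expr <- generate_expression(ann$transcripts, ann$truth, cfg)
  sw1 <- detect_switches(call_major_isoforms(expr, ann$transcripts))
  # relabel: permute transcript ids consistently in models and matrix
  ids <- ann$transcripts$transcript_id
  new_ids <- paste0("X", ids)
  tx2 <- ann$transcripts
  tx2$transcript_id <- new_ids
  vals2 <- expr$values
  rownames(vals2) <- paste0("X", rownames(vals2))
  expr2 <- expression_matrix(vals2, expr$design)
  sw2 <- detect_switches(call_major_isoforms(expr2, tx2))
  expect_equal(nrow(sw1), nrow(sw2))
  expect_setequal(paste0("X", sw1$former), sw2$former)
  expect_setequal(paste0("X", sw1$latter), sw2$latter)
})

test_that("the exact signed-rank test reproduces closed-form and reference
           values", {
  # all pairs equal -> no signed ranks -> p = 1
  expect_equal(wilcoxon_signed_rank(rep(5, 8), rep(5, 8))$p_value, 1)
  # 10 identical positive differences: one-sided 1/2^10, doubled
  w <- wilcoxon_signed_rank(1:10 + 300, 1:10)
  expect_equal(w$p_value, 2 / 2^10)
  expect_equal(w$method, "exact")
  # tie-free case agrees with stats::wilcox.test exact p
  set.seed(4)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value)
  # exact distribution equals brute-force enumeration over all sign flips,
  # including under tied absolute differences
  set.seed(9)
  for (case in 1:3) {
    d <- sample(c(-2, 2, 2, -3, 5, 5, 8, -8, 13, 21, 34, 55))
    if (case > 1) d <- d + sample(-1:1, 12, TRUE)
    d <- d[d != 0]
    n <- length(d)
    y <- sample(100:200, n, TRUE)
    x <- y + d
    ours <- wilcoxon_signed_rank(x, y)
    r <- rank(abs(d))
    V_obs <- sum(r[d > 0])
    vs <- vapply(0:(2^n - 1), function(mask) {
      sgn <- bitwAnd(mask, 2^(0:(n - 1))) > 0
      sum(r[sgn])
    }, numeric(1))
    p_brute <- min(1, 2 * min(mean(vs <= V_obs), mean(vs >= V_obs)))
    expect_equal(ours$statistic, V_obs)
    expect_equal(ours$p_value, p_brute)
  }
})

test_that("former/latter comparison pairs lengths and flags low power", {
  tx <- mk_tx(c("L.1", "L.2"),
              list(c(0, 120, 200, 320), c(0, 320)),
              locus = "L", cds_start = c(0L, 0L), cds_end = c(120L, 300L))
  sw <- tibble::tibble(locus_id = "L", former = "L.1", latter = "L.2")
  got <- compare_former_latter(sw, tx)
  expect_equal(got$table$cds_length_former, 120)
  expect_equal(got$table$cds_length_latter, 300)
  expect_true(got$low_power)
  # equal lengths for every pair -> p = 1
  sw10 <- tibble::tibble(locus_id = rep("L", 10), former = "L.1",
                         latter = "L.1")
  expect_equal(compare_former_latter(sw10, tx)$p_cds_length, 1)
})
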