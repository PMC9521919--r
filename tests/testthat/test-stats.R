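test_that("complete separation gives U = 0, and only then", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u_value, 0)
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$u_value, 0)
  # any overlap or cross-group tie lifts U above 0
  expect_gt(mann_whitney_u(c(1, 2, 5), c(4, 6, 7))$u_value, 0)
  expect_gt(mann_whitney_u(c(1, 2, 3), c(3, 4, 5))$u_value, 0)
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "dilicat_validation_error")
})

test_that("U is symmetric, complementary, and matches pair counting", {
  set.seed(21)
  for (i in 1:500) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    # integer-valued samples so ties occur regularly
    x <- sample.int(10, n1, replace = TRUE)
    y <- sample.int(10, n2, replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$u_value, oracle_u(x, y))
    expect_equal(res$u_value, mann_whitney_u(y, x)$u_value)
    expect_equal(res$U1 + res$U2, n1 * n2)
    expect_gte(res$u_value, 0)
    expect_lte(res$u_value, n1 * n2 / 2)
  }
})

test_that("p-values agree with the reference implementation", {
  set.seed(22)
  # tie-free: exact route against wilcox.test's exact p
  for (i in 1:20) {
    x <- stats::rnorm(sample(4:10, 1)); y <- stats::rnorm(sample(4:10, 1), 0.5)
    res <- mann_whitney_u(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # tied data: tie-corrected normal approximation (no continuity correction)
  for (i in 1:20) {
    x <- sample.int(6, 15, replace = TRUE); y <- sample.int(6, 12, replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$method, "normal-approximation")
    expect_equal(res$p_value,
                 stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  }
  # all values identical across both groups: defined, not significant
  expect_equal(mann_whitney_u(rep(3, 5), rep(3, 4))$p_value, 1)
})

test_that("weighting selection picks the lowest-U feature deterministically", {
  set.seed(23)
  # only the R-value distributions are disjoint: forced minimum
  a <- data.frame(drug = "a", latency_days = runif(12, 10, 60),
                  r_value = runif(12, 10, 20), ast_alt_ratio = runif(12, 0.3, 1.5))
  b <- data.frame(drug = "b", latency_days = runif(10, 10, 60),
                  r_value = runif(10, 1, 5), ast_alt_ratio = runif(10, 0.3, 1.5))
  sel <- select_weighted_feature(a, b)
  expect_equal(sel$feature, "r_value")
  expect_equal(sel$tests$r_value$u_value, 0)

  # identical cohorts in all features: tie broken by the fixed priority order
  sel_tie <- select_weighted_feature(a, a)
  expect_equal(sel_tie$feature, "latency")
  u <- vapply(sel_tie$tests, function(t) t$u_value, numeric(1))
  expect_true(all(u == u[1]))
  # deterministic and invariant to within-cohort row order
  for (i in 1:5) {
    expect_equal(select_weighted_feature(a[sample(nrow(a)), ], b[sample(nrow(b)), ])$feature,
                 "r_value")
  }
})

test_that("trend statistic matches the closed form and the table oracle", {
  # identical distributions: no trend
  res <- mh_trend_test(c(10, 20, 20, 40), c(10, 20, 20, 40))
  expect_lt(res$statistic, 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-6)

  # perfectly separated constant groups: |r| = 1, statistic = N - 1
  res <- mh_trend_test(rep(60, 9), rep(-10, 14))
  expect_equal(res$statistic, 22)
  expect_false(res$degenerate)

  # random 2 x K tables against the margin-based linear-by-linear oracle
  set.seed(24)
  for (i in 1:500) {
    a <- sample(seq(-40, 80, by = 5), sample(3:20, 1), replace = TRUE)
    b <- sample(seq(-40, 80, by = 5), sample(3:20, 1), replace = TRUE)
    res <- mh_trend_test(a, b)
    expect_equal(res$statistic, oracle_trend(a, b), tolerance = 1e-10)
    expect_gte(res$statistic, 0)
    expect_lte(res$statistic, length(a) + length(b) - 1 + 1e-10)
  }
})

test_that("trend statistic is invariant under affine bin relabelling", {
  set.seed(25)
  for (i in 1:20) {
    a <- sample(seq(-40, 80, by = 5), 12, replace = TRUE)
    b <- sample(seq(-40, 80, by = 5), 15, replace = TRUE)
    # bin lower edges are 5 * index: same statistic by affine invariance
    expect_equal(mh_trend_test(a, b)$statistic,
                 mh_trend_test(5 * floor(a / 5), 5 * floor(b / 5), bin_width = 5)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("degenerate trend input is flagged, not an error", {
  res <- mh_trend_test(c(20, 20), c(21, 22, 24))  # all scores in one 5-point bin
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(mh_trend_test(numeric(0), 1:3), class = "dilicat_validation_error")
})

test_that("pairwise comparison wires phenotype, weighting, scoring and trend together", {
  set.seed(26)
  # disjoint latencies force latency weighting and wide score separation
  a <- data.frame(drug = "a", latency_days = runif(20, 100, 400),
                  r_value = runif(20, 5, 20), ast_alt_ratio = runif(20, 0.5, 1.5))
  b <- data.frame(drug = "b", latency_days = runif(18, 5, 30),
                  r_value = runif(18, 5, 20), ast_alt_ratio = runif(18, 0.5, 1.5))
  cmp <- compare_drugs(a, b)
  expect_equal(cmp$weighted_feature, "latency")
  expect_equal(cmp$per_feature$latency$u_value, 0)
  # cohort B scores outside-range on the doubled feature: >= 40-point gap
  expect_gte(cmp$summary_a$median_weighted - cmp$summary_b$median_weighted, 40)
  expect_lt(cmp$trend$p_value, 0.001)

  # a drug compared with itself shows no trend
  self <- compare_drugs(a, a)
  expect_lt(self$trend$statistic, 1e-12)

  # comparison report round-trip keeps the headline numbers
  f <- withr::local_tempfile(fileext = ".json")
  write_comparison(cmp, f, seed = 5)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$weighted_feature, "latency")
  expect_equal(rep$median_weighted_a, cmp$summary_a$median_weighted)
  expect_equal(rep$trend$statistic, cmp$trend$statistic)
  expect_equal(rep$schema_version, "1.0")
})
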