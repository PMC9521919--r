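ph100 <- dili_phenotype(cases_from_values(1:100))
fp100 <- ph100$features$latency

test_that("the point-allocation table is internally consistent", {
  tab <- dili_band_table()
  expect_equal(tab$points, as.integer(20 * tab$fraction))
  expect_setequal(tab$points, c(20L, 10L, 5L, 0L, -5L, -10L))
})

test_that("each percentile band yields its tabulated points", {
  # knots of 1..100: p10 10.9, p15 15.85, p25 25.75, p75 75.25, p85 85.15, p90 90.1
  expect_equal(allocate_points(50.5, fp100)$points, 20)    # at the median
  expect_equal(allocate_points(25.75, fp100)$points, 20)   # exactly at p25: centre-closed
  expect_equal(allocate_points(75.25, fp100)$points, 20)   # exactly at p75
  expect_equal(allocate_points(20, fp100)$points, 10)      # 15th-25th percentile
  expect_equal(allocate_points(80, fp100)$points, 10)      # 75th-85th percentile
  expect_equal(allocate_points(12, fp100)$points, 5)       # 10th-15th percentile
  expect_equal(allocate_points(88, fp100)$points, 5)       # 85th-90th percentile
  expect_equal(allocate_points(3, fp100)$points, 0)        # 10th percentile to minimum
  expect_equal(allocate_points(95, fp100)$points, 0)       # 90th percentile to maximum
  expect_equal(allocate_points(1, fp100)$points, 0)        # range endpoints are in-range
  expect_equal(allocate_points(100, fp100)$points, 0)
  expect_equal(allocate_points(-10, fp100)$points, -5)     # outside range, within fence
  expect_equal(allocate_points(130, fp100)$points, -5)
  expect_equal(allocate_points(-80, fp100)$points, -10)    # outside range and outlier
  expect_equal(allocate_points(500, fp100)$points, -10)
  expect_error(allocate_points(NaN, fp100), class = "dilicat_validation_error")
})

test_that("a degenerate phenotype scores its point mass as core, off-values -5", {
  ph <- dili_phenotype(cases_from_values(rep(3, 4)))
  fp <- ph$features$latency
  expect_equal(allocate_points(3, fp)$points, 20)
  expect_equal(allocate_points(4, fp)$points, -5)   # eps = 0: never an outlier
  expect_equal(allocate_points(1e6, fp)$points, -5)
  # with a positive epsilon margin, far values become outliers
  ph_eps <- dili_phenotype(cases_from_values(rep(3, 4)), degenerate_eps = 2)
  expect_equal(allocate_points(4, ph_eps$features$latency)$points, -5)
  expect_equal(allocate_points(10, ph_eps$features$latency)$points, -10)
})

test_that("a fence tighter than the range enables the outlier-within band", {
  fp <- feature_phenotype(fp100$knots, n = 100, lower_fence = 5, upper_fence = 93)
  a <- allocate_points(c(2, 95, 50), fp)
  expect_equal(a$band, c("outlier_within", "outlier_within", "core"))
  expect_equal(a$points, c(-5, -5, 20))
})

test_that("allocation matches the interval-enumeration oracle on random phenotypes", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    vals <- sample.int(30, n, replace = TRUE)
    ph <- dili_phenotype(cases_from_values(vals))
    fp <- ph$features$latency
    probes <- c(vals, fp$knots, fp$lower_fence - 1, fp$upper_fence + 1,
                runif(30, fp$lower_fence - 10, fp$upper_fence + 10))
    got <- allocate_points(probes, fp)$points
    want <- vapply(probes, oracle_band_points, integer(1), fp = fp)
    expect_equal(got, as.numeric(want))
  }
})

test_that("points are non-increasing away from the IQR and every value gets a band", {
  set.seed(12)
  for (i in 1:30) {
    ph <- dili_phenotype(cases_from_values(round(stats::rlnorm(sample(3:25, 1), 2, 1), 2)))
    fp <- ph$features$latency
    span <- fp$upper_fence - fp$lower_fence + 1
    up <- sort(runif(50, fp$knots[["p75"]], fp$upper_fence + span))
    down <- sort(runif(50, fp$lower_fence - span, fp$knots[["p25"]]), decreasing = TRUE)
    expect_true(all(diff(allocate_points(up, fp)$points) <= 0))
    expect_true(all(diff(allocate_points(down, fp)$points) <= 0))
    anywhere <- runif(100, fp$lower_fence - span, fp$upper_fence + span)
    alloc <- allocate_points(anywhere, fp)
    expect_true(all(alloc$band %in% dili_band_table()$band))
    expect_true(all(alloc$points %in% dili_band_table()$points))
  }
})

test_that("weighted totals follow the doubling rule", {
  # all three features at the medians: 20 each, doubled feature gives 80
  s <- score_case(50.5, 50.5, 50.5, ph100, weighted_feature = "latency")
  expect_equal(unname(unlist(s[paste0(dilicat:::dc_features(), "_points")])),
               c(20L, 20L, 20L))
  expect_equal(s$weighted_total, 80L)
  expect_equal(s$unweighted_total, 60L)

  # all features far below the minima, past the fences: 2*(-10) + (-10) + (-10)
  # (a high-valued phenotype keeps the lower fence positive, so the probe case
  # can sit below it while still being a valid clinical record)
  ph_hi <- dili_phenotype(cases_from_values(seq(200, 300)))
  expect_lt(50, ph_hi$features$latency$lower_fence)
  s <- score_case(50, 50, 50, ph_hi, weighted_feature = "r_value")
  expect_equal(s$weighted_total, -40L)

  # no weighting: weighted total equals the plain sum
  s <- score_case(50.5, 20, 3, ph100)  # subscores 20, 10, 0
  expect_equal(s$unweighted_total, 30L)
  expect_equal(s$weighted_total, 30L)

  expect_error(predict(ph100, cases_from_values(c(10, 20)),
                       weighted_feature = "bogus"))
})

test_that("cohort medians agree with brute-force per-case recomputation", {
  set.seed(13)
  cohort <- rand_cases(21)
  ph <- dili_phenotype(rand_cases(15, "ref"), drug = "ref")
  scored <- score_cohort(cohort, ph, weighted_feature = "ast_alt_ratio")
  per_case <- vapply(seq_len(nrow(cohort)), function(i) {
    s <- score_case(cohort$latency_days[i], cohort$r_value[i],
                    cohort$ast_alt_ratio[i], ph,
                    weighted_feature = "ast_alt_ratio")
    s$weighted_total
  }, integer(1))
  expect_equal(scored$summary$median_weighted, median(per_case))
  expect_true(all(scored$scores$weighted_total >= -40 &
                  scored$scores$weighted_total <= 80))

  # a cohort of one repeated case has median equal to that case's score
  one <- cohort[rep(2, 7), ]
  expect_equal(score_cohort(one, ph)$summary$median_weighted,
               per_case_median <- score_cohort(cohort[2, , drop = FALSE], ph)$summary$median_weighted)
  expect_error(predict(ph, cohort[0, ]), class = "dilicat_validation_error")
})

test_that("scoring a series against its own phenotype gives median subscores of 20", {
  # The diagonal 20/20/20: whenever more than half of a feature's values lie
  # in the closed IQR, the median self-subscore is the full 20. For distinct
  # values under the type-7 estimator this holds exactly when n = 4k + 1
  # ((n+1)/2 order statistics fall in [p25, p75]); tied data concentrates
  # additional mass in the IQR, which is why real case series show it broadly.
  set.seed(14)
  for (n in c(13, 17, 21, 29, 37)) {
    cases <- rand_cases(n)
    s <- summary(predict(dili_phenotype(cases), cases))
    expect_equal(unname(s$median_subscores), c(20, 20, 20))
  }
  # general premise-conditioned form, including tied integer data
  for (i in 1:15) {
    vals <- sample.int(12, sample(8:30, 1), replace = TRUE)
    cases <- cases_from_values(vals)
    ph <- dili_phenotype(cases)
    k <- ph$features$latency$knots
    s <- summary(predict(ph, cases))
    if (mean(vals >= k[["p25"]] & vals <= k[["p75"]]) > 0.5) {
      expect_equal(unname(s$median_subscores["latency"]), 20)
    }
  }
})

test_that("theoretical bounds track the enabled adjudication extensions", {
  expect_equal(theoretical_bounds(adjudication_config()),
               c(min = -40, max = 80))
  expect_equal(theoretical_bounds(adjudication_config(TRUE, TRUE)),
               c(min = -65, max = 125))
  expect_equal(theoretical_bounds(adjudication_config(enable_competing_causes = TRUE)),
               c(min = -65, max = 105))
  expect_equal(theoretical_bounds(adjudication_config(enable_hepatotoxicity = TRUE)),
               c(min = -40, max = 100))
})
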