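#' The DILI-CAT point-allocation table
#'
#' Points are a fixed fraction of the 20-point full credit, according to where
#' a case value falls relative to the drug's feature distribution: within the
#' IQR (the "50% core interval") 100% = 20 points; between the 15th-25th or
#' 75th-85th percentiles 50% = 10; between the 10th-15th or 85th-90th
#' percentiles 25% = 5; from the 10th percentile to the minimum or the 90th to
#' the maximum 0% = 0; outside the observed range -25% = -5; and -50% = -10
#' when the value is both outside the range and an outlier (beyond the fence).
#' The `outlier_within` row (-5) covers the configuration where a fence is
#' placed inside the observed range, so the standalone outlier deduction is
#' reachable too.
#'
#' @return A data frame with columns `band`, `fraction`, `points`;
#'   `points == 20 * fraction` in every row.
#' @export
dili_band_table <- function() {
  data.frame(
    band = c("core", "near", "far", "tail", "outside", "outlier_within",
             "outside_outlier"),
    fraction = c(1, 0.5, 0.25, 0, -0.25, -0.25, -0.5),
    points = c(20L, 10L, 5L, 0L, -5L, -5L, -10L),
    stringsAsFactors = FALSE
  )
}

#' Allocate DILI-CAT points to case values against a feature phenotype
#'
#' Places each value into exactly one percentile band of the feature's
#' distribution and returns the band and its points. Band boundaries are
#' closed toward the centre: a value exactly at a percentile knot takes the
#' more central (more favourable) band, so a value at the 25th or 75th
#' percentile scores the full 20.
#'
#' For a degenerate profile (all knots equal, zero IQR) the fences collapse
#' to the range; any value off the point mass is outside-range (-5) and is an
#' outlier only if it is more than `degenerate_eps` away (default 0: never).
#'
#' @param value numeric vector of case values; must be finite.
#' @param fp a `dili_feature` (see [feature_phenotype()]).
#' @return A data frame with one row per value: `value`, `band`, `fraction`,
#'   `points`.
#' @examples
#' fp <- feature_phenotype(stats::quantile(1:100, c(0,.1,.15,.25,.5,.75,.85,.9,1)),
#'                         n = 100)
#' allocate_points(c(50, 20, 12, 3, -20, -200), fp)
#' @export
allocate_points <- function(value, fp) {
  stopifnot(inherits(fp, "dili_feature"))
  dc_assert_finite(value, "`value`")
  k <- fp$knots
  degenerate <- (k[["p75"]] - k[["p25"]]) == 0  # fences collapse to the range

  in_range <- value >= k[["min"]] & value <= k[["max"]]
  if (degenerate) {
    eps <- fp$degenerate_eps
    outlier <- if (eps > 0) {
      value < fp$lower_fence - eps | value > fp$upper_fence + eps
    } else {
      rep(FALSE, length(value))
    }
  } else {
    outlier <- value < fp$lower_fence | value > fp$upper_fence
  }

  band <- character(length(value))
  core <- value >= k[["p25"]] & value <= k[["p75"]]
  near <- !core & value >= k[["p15"]] & value <= k[["p85"]]
  far <- !core & !near & value >= k[["p10"]] & value <= k[["p90"]]
  tl <- in_range & !core & !near & !far
  band[core] <- "core"
  band[near] <- "near"
  band[far] <- "far"
  band[tl] <- "tail"
  band[!in_range] <- ifelse(outlier[!in_range], "outside_outlier", "outside")
  # Fences tighter than the range: an in-range value beyond a fence still
  # takes the standalone outlier deduction.
  band[in_range & outlier & !core] <- "outlier_within"

  tab <- dili_band_table()
  i <- match(band, tab$band)
  data.frame(value = value, band = band, fraction = tab$fraction[i],
             points = tab$points[i], stringsAsFactors = FALSE)
}

#' Score cases against a fitted drug phenotype
#'
#' The scoring engine: each case's latency, R-value and AST/ALT ratio is
#' placed in the phenotype's percentile bands via [allocate_points()], giving
#' three subscores in \{20, 10, 5, 0, -5, -10\}. The unweighted total is their
#' sum; when a weighted feature is set (normally the feature with the lowest
#' Mann-Whitney U against a comparator drug, see [select_weighted_feature()]),
#' that subscore is doubled, so the weighted total lies in \[-40, 80\].
#'
#' @param object a `dili_phenotype`.
#' @param newdata a case table (see [dili_cases()]); the drug label need not
#'   match the phenotype's (scoring candidate cases against another drug's
#'   phenotype is the point of the method).
#' @param weighted_feature `"none"` (default), `"latency"`, `"r_value"` or
#'   `"ast_alt_ratio"`.
#' @param ... unused.
#' @return An object of class `dili_scores`: a data frame with one row per
#'   case (`case_id`, per-feature subscores and band names,
#'   `weighted_feature`, `unweighted_total`, `weighted_total`).
#' @examples
#' cases <- data.frame(drug = "d", latency_days = c(8, 10, 12, 15, 20),
#'                     r_value = c(2, 3, 5, 6, 8),
#'                     ast_alt_ratio = c(.5, .6, .8, .9, 1.2))
#' ph <- dili_phenotype(cases)
#' predict(ph, cases, weighted_feature = "latency")
#' @export
predict.dili_phenotype <- function(object, newdata,
                                   weighted_feature = c("none", "latency",
                                                        "r_value", "ast_alt_ratio"),
                                   ...) {
  weighted_feature <- match.arg(weighted_feature)
  cases <- dili_cases(newdata)
  if (nrow(cases) == 0) dc_validation_error("no cases to score")
  cols <- dc_feature_cols()
  out <- data.frame(case_id = cases$case_id, drug = cases$drug,
                    stringsAsFactors = FALSE)
  for (f in dc_features()) {
    alloc <- allocate_points(cases[[cols[[f]]]], object$features[[f]])
    out[[paste0(f, "_points")]] <- alloc$points
    out[[paste0(f, "_band")]] <- alloc$band
  }
  subs <- as.matrix(out[paste0(dc_features(), "_points")])
  out$weighted_feature <- weighted_feature
  out$unweighted_total <- as.integer(rowSums(subs))
  out$weighted_total <- out$unweighted_total +
    if (weighted_feature == "none") 0L else out[[paste0(weighted_feature, "_points")]]
  structure(out, class = c("dili_scores", "data.frame"),
            phenotype_drug = object$drug)
}

#' @export
print.dili_scores <- function(x, ...) {
  cat(sprintf("DILI-CAT scores against the %s phenotype (%d cases, weighting: %s)\n",
              attr(x, "phenotype_drug"), nrow(x), x$weighted_feature[1]))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Summarise a scored cohort
#'
#' Cohort medians as reported for each drug pair: the median subscore per
#' clinical feature and the median unweighted and weighted totals, under the
#' same median convention as phenotype fitting.
#'
#' @param object a `dili_scores` object from [predict.dili_phenotype()].
#' @param quantile_type median convention (7 or 6; they agree at p = 0.5).
#' @param ... unused.
#' @return A list with `n`, `weighted_feature`, `median_subscores` (named
#'   numeric), `median_unweighted`, `median_weighted`.
#' @export
summary.dili_scores <- function(object, quantile_type = 7, ...) {
  subs <- vapply(dc_features(), function(f) {
    dc_median(object[[paste0(f, "_points")]], quantile_type = quantile_type)
  }, numeric(1))
  res <- list(n = nrow(object),
              weighted_feature = object$weighted_feature[1],
              median_subscores = subs,
              median_unweighted = dc_median(object$unweighted_total, quantile_type),
              median_weighted = dc_median(object$weighted_total, quantile_type))
  class(res) <- "summary.dili_scores"
  res
}

#' @export
print.summary.dili_scores <- function(x, ...) {
  cat(sprintf("n = %d, weighting: %s\n", x$n, x$weighted_feature))
  cat("median subscores:\n")
  print(round(x$median_subscores, 2))
  cat(sprintf("median weighted total: %.1f\n", x$median_weighted))
  invisible(x)
}

#' Score one case
#'
#' Convenience wrapper around [predict.dili_phenotype()] for a single case
#' given as bare feature values.
#'
#' @param latency_days,r_value,ast_alt_ratio the case's onset features.
#' @param phenotype a `dili_phenotype`.
#' @param weighted_feature as in [predict.dili_phenotype()].
#' @param case_id label for the case.
#' @return A one-row `dili_scores` data frame.
#' @export
score_case <- function(latency_days, r_value, ast_alt_ratio, phenotype,
                       weighted_feature = "none", case_id = "case_1") {
  predict(phenotype,
          data.frame(case_id = case_id, drug = phenotype$drug,
                     latency_days = latency_days, r_value = r_value,
                     ast_alt_ratio = ast_alt_ratio),
          weighted_feature = weighted_feature)
}

#' Score a cohort and summarise it
#'
#' @param cases a case table.
#' @param phenotype a `dili_phenotype`.
#' @param weighted_feature as in [predict.dili_phenotype()].
#' @return A list with `scores` (the per-case `dili_scores`) and `summary`
#'   (see [summary.dili_scores()]).
#' @export
score_cohort <- function(cases, phenotype, weighted_feature = "none") {
  scores <- predict(phenotype, cases, weighted_feature = weighted_feature)
  list(scores = scores,
       summary = summary(scores, quantile_type = phenotype$config$quantile_type))
}

#' Theoretical DILI-CAT score bounds
#'
#' Extremes of the weighted total (one subscore doubled, each subscore in
#' \[-10, 20\]) give \[-40, 80\]; enabled adjudication extensions shift the
#' bounds by the extremes of their rubrics (competing causes -25..25,
#' hepatotoxicity propensity 0..20), so with both enabled the full
#' adjudication score spans \[-65, 125\].
#'
#' @param config an [adjudication_config()].
#' @return Named numeric vector `c(min = , max = )`.
#' @examples
#' theoretical_bounds(adjudication_config())
#' theoretical_bounds(adjudication_config(enable_competing_causes = TRUE,
#'                                        enable_hepatotoxicity = TRUE))
#' @export
theoretical_bounds <- function(config = adjudication_config()) {
  stopifnot(inherits(config, "dili_adjudication_config"))
  pts <- dili_band_table()$points
  lo <- 3 * min(pts) + min(pts)   # weighted feature counts twice
  hi <- 3 * max(pts) + max(pts)
  if (config$enable_competing_causes) {
    lo <- lo + min(config$competing_rubric)
    hi <- hi + max(config$competing_rubric)
  }
  if (config$enable_hepatotoxicity) {
    lo <- lo + min(config$hepatotoxicity_rubric)
    hi <- hi + max(config$hepatotoxicity_rubric)
  }
  c(min = lo, max = hi)
}
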