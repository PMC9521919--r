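#' Mann-Whitney U rank test between two feature samples
#'
#' Computes the Mann-Whitney U statistic with midranks for ties and reports
#' `u_value = min(U1, U2)`, so the smaller the U, the greater the difference
#' between the two distributions; U = 0 reflects complete separation (every
#' value in one sample beyond every value in the other). This is the reading
#' used to pick the weighted feature of a drug pair.
#'
#' The two-sided p-value uses the exact U distribution when both samples are
#' small (`n1 * n2 <= 400`) and tie-free, and otherwise the normal
#' approximation with the tie-corrected variance
#' `n1 n2 / 12 * (N + 1 - sum(t^3 - t) / (N (N - 1)))`
#' (no continuity correction).
#'
#' @param x,y numeric samples; both non-empty and finite.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   default `NULL` chooses automatically as above.
#' @return An object of class `dili_utest`: `u_value`, `U1`, `U2`, `n1`,
#'   `n2`, `p_value`, `method` (`"exact"` or `"normal-approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u_value  # complete separation: 0
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) dc_validation_error("both samples must be non-empty")
  dc_assert_finite(x, "`x`"); dc_assert_finite(y, "`y`")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  u <- min(U1, U2)

  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  use_exact <- exact %||% (!has_ties && n1 * n2 <= 400)
  if (use_exact && has_ties) use_exact <- FALSE

  if (use_exact) {
    p <- if (U1 > n1 * n2 / 2) {
      2 * stats::pwilcox(U1 - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U1, n1, n2)
    }
    method <- "exact"
  } else {
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal-approximation"
  }
  structure(list(u_value = u, U1 = U1, U2 = U2, n1 = n1, n2 = n2,
                 p_value = min(1, p), method = method),
            class = "dili_utest")
}

#' @export
print.dili_utest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$u_value, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Select the weighted feature for a drug pair
#'
#' Runs the Mann-Whitney rank test on each of the three clinical features
#' between two cohorts and returns the feature with the greatest
#' discriminating potential, defined by the lowest U-value; that feature's
#' subscore is doubled in the pairwise DILI-CAT scoring. Ties in U are broken
#' by the fixed priority latency > R-value > AST/ALT ratio.
#'
#' @param cases_a,cases_b case tables (see [dili_cases()]).
#' @param exact passed to [mann_whitney_u()].
#' @return A list with `feature` (the selected label) and `tests` (a named
#'   list of `dili_utest`, one per feature).
#' @export
select_weighted_feature <- function(cases_a, cases_b, exact = NULL) {
  a <- dili_cases(cases_a); b <- dili_cases(cases_b)
  cols <- dc_feature_cols()
  tests <- lapply(dc_features(), function(f) {
    mann_whitney_u(a[[cols[[f]]]], b[[cols[[f]]]], exact = exact)
  })
  names(tests) <- dc_features()
  u <- vapply(tests, function(t) t$u_value, numeric(1))
  # which.min returns the first minimum, i.e. the dc_features() priority order
  list(feature = dc_features()[which.min(u)], tests = tests)
}

#' Mantel-Haenszel test for trend on binned DILI-CAT scores
#'
#' Compares two score distributions by treating five-point score increments
#' as ordinal categories (bin index `floor(score / 5)`) and testing for a
#' linear trend across the ordered 2 x K table: the statistic is
#' `(N - 1) * r^2` with `r` the Pearson correlation between the group
#' indicator and the ordinal bin score, referred to chi-square with 1 df.
#' The higher the statistic, the greater the difference between the two
#' score distributions. The statistic is invariant under positive affine
#' transforms of the bin scores, so using bin indices versus bin lower edges
#' is immaterial.
#'
#' Degenerate input (one of the margins has zero variance: a single group, or
#' all scores in one bin) yields statistic 0, p-value 1 and `degenerate = TRUE`.
#'
#' @param scores_a,scores_b numeric score vectors, both non-empty.
#' @param bin_width width of the ordinal score bins. Default 5.
#' @return An object of class `dili_trend`: `statistic`, `p_value`,
#'   `n_categories`, `degenerate`.
#' @export
mh_trend_test <- function(scores_a, scores_b, bin_width = 5) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    dc_validation_error("both score lists must be non-empty")
  }
  dc_assert_finite(scores_a, "`scores_a`"); dc_assert_finite(scores_b, "`scores_b`")
  bins <- floor(c(scores_a, scores_b) / bin_width)
  g <- rep(c(0, 1), c(length(scores_a), length(scores_b)))
  N <- length(g)
  degenerate <- length(unique(g)) < 2 || length(unique(bins)) < 2 || N < 2
  if (degenerate) {
    stat <- 0; p <- 1
  } else {
    r <- stats::cor(g, bins)
    stat <- (N - 1) * r^2
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p,
                 n_categories = length(unique(bins)),
                 n = N, degenerate = degenerate),
            class = "dili_trend")
}

#' @export
print.dili_trend <- function(x, ...) {
  cat(sprintf("Mantel-Haenszel trend chi-square(1) = %.3f, p = %.4g (%d ordinal categories%s)\n",
              x$statistic, x$p_value, x$n_categories,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Pairwise drug comparison with a drug-specific DILI-CAT
#'
#' The full pairwise procedure: fit the phenotype from drug A's cases, pick
#' the weighted feature from the A-versus-B Mann-Whitney tests (lowest U),
#' score both cohorts against the A phenotype with that weighting, and test
#' the two weighted-score distributions with the Mantel-Haenszel trend test
#' on five-point score bins.
#'
#' @param cases_a,cases_b case tables; the phenotype is derived from
#'   `cases_a` (drug A's own DILI-CAT scoring).
#' @param weighted_feature override the data-driven weighting selection;
#'   default `NULL` selects by lowest U.
#' @param exact passed to [mann_whitney_u()].
#' @param ... passed to [dili_phenotype()] (e.g. `quantile_type`, `outlier_k`).
#' @return An object of class `dili_comparison`: drug labels, `per_feature`
#'   rank tests, `weighted_feature`, the two `dili_scores` objects, their
#'   summaries, and `trend`.
#' @examples
#' a <- data.frame(drug = "A", latency_days = c(100, 120, 150, 200, 240),
#'                 r_value = c(8, 10, 12, 15, 18), ast_alt_ratio = c(.7, .8, .8, 1, 1.2))
#' b <- data.frame(drug = "B", latency_days = c(10, 15, 20, 25, 28),
#'                 r_value = c(1, 1.2, 1.6, 2.5, 3.2), ast_alt_ratio = c(.3, .4, .4, .5, .7))
#' compare_drugs(a, b)
#' @export
compare_drugs <- function(cases_a, cases_b, weighted_feature = NULL,
                          exact = NULL, ...) {
  a <- dili_cases(cases_a); b <- dili_cases(cases_b)
  ph <- dili_phenotype(a, ...)
  sel <- select_weighted_feature(a, b, exact = exact)
  wf <- weighted_feature %||% sel$feature
  if (!wf %in% dc_features()) {
    dc_validation_error(sprintf("unknown weighted feature `%s` (valid: %s)",
                                wf, paste(dc_features(), collapse = ", ")))
  }
  scores_a <- predict(ph, a, weighted_feature = wf)
  scores_b <- predict(ph, b, weighted_feature = wf)
  trend <- mh_trend_test(scores_a$weighted_total, scores_b$weighted_total)
  structure(
    list(drug_a = unique(a$drug), drug_b = unique(b$drug),
         phenotype = ph, per_feature = sel$tests, weighted_feature = wf,
         scores_a = scores_a, scores_b = scores_b,
         summary_a = summary(scores_a, quantile_type = ph$config$quantile_type),
         summary_b = summary(scores_b, quantile_type = ph$config$quantile_type),
         trend = trend),
    class = "dili_comparison"
  )
}

#' @export
print.dili_comparison <- function(x, ...) {
  cat(sprintf("%s-DILI-CAT: %s (n = %d) vs %s (n = %d)\n",
              x$drug_a, x$drug_a, nrow(x$scores_a), x$drug_b, nrow(x$scores_b)))
  u <- vapply(x$per_feature, function(t) t$u_value, numeric(1))
  p <- vapply(x$per_feature, function(t) t$p_value, numeric(1))
  print(data.frame(feature = names(u), U = u, p = signif(p, 3), row.names = NULL))
  cat(sprintf("weighted feature: %s\n", x$weighted_feature))
  cat(sprintf("median weighted score: %s %.1f vs %s %.1f\n",
              x$drug_a, x$summary_a$median_weighted,
              x$drug_b, x$summary_b$median_weighted))
  print(x$trend)
  invisible(x)
}

#' Write a pairwise comparison report
#'
#' Serialises a [compare_drugs()] result as structured text (JSON): per-feature
#' U and p, the chosen weighting, per-cohort median weighted scores, and the
#' trend statistic and p, plus tool version / config hash / seed provenance.
#'
#' @param comparison a `dili_comparison`.
#' @param path file path.
#' @param seed optional integer recorded for provenance.
#' @export
write_comparison <- function(comparison, path, seed = NULL) {
  stopifnot(inherits(comparison, "dili_comparison"))
  payload <- list(
    schema_version = dc_schema_version,
    tool = paste0("dilicat ", as.character(utils::packageVersion("dilicat"))),
    config_hash = rlang::hash(comparison$phenotype$config),
    seed = seed,
    drug_a = comparison$drug_a, drug_b = comparison$drug_b,
    weighted_feature = comparison$weighted_feature,
    per_feature = lapply(comparison$per_feature, function(t) {
      list(u_value = t$u_value, p_value = t$p_value, method = t$method)
    }),
    median_weighted_a = comparison$summary_a$median_weighted,
    median_weighted_b = comparison$summary_b$median_weighted,
    median_subscores_a = as.list(comparison$summary_a$median_subscores),
    median_subscores_b = as.list(comparison$summary_b$median_subscores),
    trend = list(statistic = comparison$trend$statistic,
                 p_value = comparison$trend$p_value,
                 n_categories = comparison$trend$n_categories,
                 degenerate = comparison$trend$degenerate)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
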