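#' Draw values from a 9-knot quantile profile
#'
#' Inverse-CDF sampling through the piecewise-linear CDF interpolating the
#' points (0, min), (.10, p10), (.15, p15), (.25, p25), (.50, median),
#' (.75, p75), (.85, p85), (.90, p90), (1, max). Samples are i.i.d., always
#' lie in \[min, max\], and their empirical quantiles converge to the knots as
#' n grows — which is what makes the generator a faithful stand-in for a case
#' series with a prescribed phenotype.
#'
#' @param knots 9 non-decreasing values (see [feature_phenotype()]), or a
#'   `dili_feature` whose knots are used.
#' @param n number of draws.
#' @param u optional uniform(0,1) draws to transform (used internally to
#'   correlate features); by default `n` fresh draws from the session RNG.
#' @return Numeric vector of length `n`.
#' @export
sample_from_quantiles <- function(knots, n, u = NULL) {
  if (inherits(knots, "dili_feature")) knots <- knots$knots
  dc_assert_finite(knots, "`knots`")
  if (length(knots) != 9 || is.unsorted(knots)) {
    dc_validation_error("`knots` must be 9 non-decreasing values")
  }
  if (!is.numeric(n) || n < 1) dc_validation_error("`n` must be >= 1")
  u <- u %||% stats::runif(n)
  if (all(knots == knots[1])) return(rep(as.numeric(knots[1]), length(u)))
  # approx() requires strictly its x to be ordered; duplicated knot values are
  # fine (flat CDF segments map an interval of u to one value).
  stats::approx(x = dc_probs(), y = as.numeric(knots), xout = u,
                ties = "ordered")$y
}

#' Simulate synthetic case series from a fitted phenotype
#'
#' Generates cohorts whose per-feature empirical quantiles match the
#' phenotype's knot profile, via [sample_from_quantiles()]. Features are
#' drawn independently by default; `copula_rho` turns on an exchangeable
#' Gaussian copula between the three features for sensitivity analyses
#' (the published case series report no inter-feature correlations, hence
#' independence as the default).
#'
#' @param object a `dili_phenotype`.
#' @param nsim number of cohorts to generate. Default 1.
#' @param seed integer seed; when given, the RNG state is set before sampling
#'   and restored afterwards, so the output is a pure function of the seed.
#' @param n cases per cohort; defaults to the phenotype's `n_cases`.
#' @param copula_rho pairwise latent Gaussian correlation in (-0.5, 1);
#'   0 (default) draws features independently.
#' @param digits optional named vector of reporting precisions, e.g.
#'   `c(latency = 0, r_value = 1, ast_alt_ratio = 1)`, emulating how case
#'   series print their data (whole-day latencies, one-decimal ratios).
#'   Rounded values are clamped to the knot range so samples never leave
#'   \[min, max\]. Default `NULL`: no rounding.
#' @param ... unused.
#' @return A case table (`nsim = 1`) or a list of case tables.
#' @export
simulate.dili_phenotype <- function(object, nsim = 1, seed = NULL,
                                    n = object$n_cases, copula_rho = 0,
                                    digits = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  if (!is.numeric(n) || n < 1) dc_validation_error("`n` must be >= 1")
  if (copula_rho <= -0.5 || copula_rho >= 1) {
    dc_validation_error("`copula_rho` must lie in (-0.5, 1)")
  }
  cols <- dc_feature_cols()
  one <- function(i) {
    u <- dc_uniforms(n, copula_rho)
    df <- data.frame(case_id = sprintf("sim_%d_%03d", i, seq_len(n)),
                     drug = object$drug, stringsAsFactors = FALSE)
    for (j in seq_along(dc_features())) {
      f <- dc_features()[j]
      v <- sample_from_quantiles(object$features[[f]], n, u = u[, j])
      if (!is.null(digits) && !is.na(digits[f])) {
        k <- object$features[[f]]$knots
        v <- pmin(pmax(round(v, digits[[f]]), k[["min"]]), k[["max"]])
      }
      df[[cols[[f]]]] <- v
    }
    dili_cases(df)
  }
  out <- lapply(seq_len(nsim), one)
  if (nsim == 1) out[[1]] else out
}

# n x 3 uniforms, independent (rho = 0) or via exchangeable Gaussian copula.
dc_uniforms <- function(n, rho) {
  if (rho == 0) {
    matrix(stats::runif(3 * n), nrow = n, ncol = 3)
  } else {
    sigma <- matrix(rho, 3, 3); diag(sigma) <- 1
    z <- matrix(stats::rnorm(3 * n), nrow = n) %*% chol(sigma)
    stats::pnorm(z)
  }
}

#' Build a phenotype directly from published summary statistics
#'
#' Constructs a `dili_phenotype` from the quantities a case series usually
#' prints — per feature the median, IQR and range — filling the unprinted
#' knots (p10, p15, p85, p90, and p25/p75 if absent) by linear interpolation
#' in probability between the nearest printed neighbours. Interpolated knots
#' are flagged in each `dili_feature` so downstream users can tell observed
#' from reconstructed values.
#'
#' @param drug drug label.
#' @param n_cases number of cases behind the published summaries.
#' @param latency,r_value,ast_alt_ratio named lists with elements `median`,
#'   `range` (length 2) and optionally `iqr` (length 2).
#' @param outlier_k IQR multiplier for fences. Default 1.5.
#' @param provenance free-text source note.
#' @return A `dili_phenotype`.
#' @export
phenotype_from_summary <- function(drug, n_cases, latency, r_value,
                                   ast_alt_ratio, outlier_k = 1.5,
                                   provenance = "") {
  specs <- list(latency = latency, r_value = r_value,
                ast_alt_ratio = ast_alt_ratio)
  features <- lapply(dc_features(), function(f) {
    s <- specs[[f]]
    probs <- dc_probs()
    knots <- rep(NA_real_, 9)
    names(knots) <- dc_knot_names()
    knots[c("min", "max")] <- s$range
    knots["median"] <- s$median
    if (!is.null(s$iqr)) knots[c("p25", "p75")] <- s$iqr
    printed <- names(knots)[!is.na(knots)]
    known_p <- probs[!is.na(knots)]
    known_v <- knots[!is.na(knots)]
    if (is.unsorted(known_v)) {
      dc_validation_error(sprintf("%s: printed quantiles are not non-decreasing", f))
    }
    knots[is.na(knots)] <- stats::approx(known_p, known_v,
                                         xout = probs[is.na(knots)])$y
    feature_phenotype(knots, n = n_cases, feature = f, outlier_k = outlier_k,
                      interpolated = setdiff(dc_knot_names(), printed))
  })
  names(features) <- dc_features()
  structure(
    list(drug = drug, n_cases = as.integer(n_cases), features = features,
         config = list(quantile_type = 7L, outlier_k = outlier_k,
                       degenerate_eps = 0, round_latency = FALSE),
         provenance = provenance, call = match.call()),
    class = "dili_phenotype"
  )
}
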