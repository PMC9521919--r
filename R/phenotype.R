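#' Construct a single-feature phenotype from quantile knots
#'
#' A feature phenotype is a 9-knot empirical quantile profile — values at
#' probabilities (0, .10, .15, .25, .50, .75, .85, .90, 1) — plus outlier
#' fences. It is the object against which [allocate_points()] places a case
#' value. Usually built by [dili_phenotype()]; this constructor is exposed so
#' phenotypes can also be assembled from published summary statistics.
#'
#' Default fences extend the observed range by `outlier_k` times the IQR:
#' `lower_fence = min - k * (p75 - p25)`, `upper_fence = max + k * (p75 - p25)`.
#' "Outlier" means beyond a fence; a value both outside the range and beyond a
#' fence takes the largest deduction. Explicit fences may be supplied (they
#' may even sit inside the observed range, enabling the outlier-within-range
#' band).
#'
#' @param knots numeric vector of 9 non-decreasing values, named or in the
#'   order `min, p10, p15, p25, median, p75, p85, p90, max`.
#' @param n number of source cases (>= 2).
#' @param feature feature label: `"latency"`, `"r_value"` or `"ast_alt_ratio"`.
#' @param outlier_k IQR multiplier for the default fences. Default 1.5.
#' @param lower_fence,upper_fence explicit fences; override the IQR rule.
#' @param degenerate_eps absolute outlier margin used when the IQR is zero
#'   (fences collapse to the range); with the default 0 no value is flagged
#'   as an outlier for a degenerate profile.
#' @param interpolated character vector of knot names whose values were
#'   filled by interpolation rather than observed (used by the shipped
#'   published-table phenotypes).
#' @return An object of class `dili_feature`.
#' @export
feature_phenotype <- function(knots, n, feature = "latency", outlier_k = 1.5,
                              lower_fence = NULL, upper_fence = NULL,
                              degenerate_eps = 0, interpolated = character()) {
  feature <- match.arg(feature, dc_features())
  dc_assert_finite(knots, "`knots`")
  if (length(knots) != 9) dc_validation_error("`knots` must have length 9")
  knots <- stats::setNames(as.numeric(knots), dc_knot_names())
  if (is.unsorted(knots)) dc_validation_error("`knots` must be non-decreasing")
  if (!is.numeric(n) || n < 2) dc_validation_error("`n` must be >= 2")
  if (!is.numeric(outlier_k) || outlier_k <= 0) {
    dc_validation_error("`outlier_k` must be positive")
  }
  iqr <- knots[["p75"]] - knots[["p25"]]
  lower_fence <- lower_fence %||% (knots[["min"]] - outlier_k * iqr)
  upper_fence <- upper_fence %||% (knots[["max"]] + outlier_k * iqr)
  if (upper_fence < lower_fence) dc_validation_error("`upper_fence` must be >= `lower_fence`")
  structure(
    list(feature = feature, knots = knots, n = as.integer(n),
         lower_fence = as.numeric(lower_fence),
         upper_fence = as.numeric(upper_fence),
         outlier_k = outlier_k, degenerate_eps = degenerate_eps,
         interpolated = as.character(interpolated)),
    class = "dili_feature"
  )
}

#' Fit a drug-specific DILI phenotype from case-level data
#'
#' Characterises a drug's liver-injury signature as the empirical quantile
#' profile of three onset features across its bona fide DILI cases: latency
#' (days from drug start to onset), R-value, and AST/ALT ratio. For each
#' feature the profile records the minimum, the 10th/15th/25th percentiles,
#' the median, the 75th/85th/90th percentiles and the maximum, plus outlier
#' fences (observed range extended by `outlier_k` IQRs). The fitted object is
#' the reference against which candidate cases are scored by [predict.dili_phenotype()].
#'
#' @param cases a case table (see [dili_cases()]); all rows must carry the
#'   same drug label — phenotypes are drug-specific by construction, so mixed
#'   labels are an error.
#' @param drug optional drug label (forwarded to [dili_cases()]).
#' @param quantile_type quantile estimator convention: 7 (linear interpolation
#'   between order statistics, the default) or 6.
#' @param outlier_k IQR multiplier for the outlier fences. Default 1.5.
#' @param degenerate_eps absolute outlier margin for zero-IQR features.
#' @param round_latency round latency to whole days before fitting.
#' @param provenance free-text note stored with the phenotype.
#' @return An object of class `dili_phenotype`: a list with the drug label,
#'   `n_cases`, one `dili_feature` per feature, and the fitting configuration.
#' @examples
#' cases <- data.frame(
#'   drug = "drugA",
#'   latency_days = c(10, 14, 20, 25, 30, 41),
#'   r_value = c(1.1, 2.3, 4.0, 5.2, 6.8, 9.0),
#'   ast_alt_ratio = c(0.4, 0.5, 0.7, 0.8, 1.1, 1.6)
#' )
#' ph <- dili_phenotype(cases)
#' coef(ph)
#' @seealso [predict.dili_phenotype()] for scoring, [simulate.dili_phenotype()]
#'   for drawing synthetic case series, [published_phenotypes()] for the four
#'   shipped drug phenotypes.
#' @export
dili_phenotype <- function(cases, drug = NULL, quantile_type = 7,
                           outlier_k = 1.5, degenerate_eps = 0,
                           round_latency = FALSE, provenance = "") {
  cases <- dili_cases(cases, drug = drug, round_latency = round_latency)
  if (nrow(cases) < 2) dc_validation_error("need at least 2 cases to build a phenotype")
  drugs <- unique(cases$drug)
  if (length(drugs) != 1) {
    dc_validation_error(sprintf("cases carry mixed drug labels: %s",
                                paste(drugs, collapse = ", ")))
  }
  quantile_type <- dc_check_quantile_type(quantile_type)
  cols <- dc_feature_cols()
  features <- lapply(dc_features(), function(f) {
    feature_phenotype(
      knots = dc_quantile(cases[[cols[[f]]]], dc_probs(), quantile_type = quantile_type),
      n = nrow(cases), feature = f, outlier_k = outlier_k,
      degenerate_eps = degenerate_eps
    )
  })
  names(features) <- dc_features()
  structure(
    list(drug = drugs, n_cases = nrow(cases), features = features,
         config = list(quantile_type = quantile_type, outlier_k = outlier_k,
                       degenerate_eps = degenerate_eps,
                       round_latency = isTRUE(round_latency)),
         provenance = provenance,
         call = match.call()),
    class = "dili_phenotype"
  )
}

#' @export
print.dili_phenotype <- function(x, ...) {
  cat(sprintf("DILI phenotype for %s (n = %d cases)\n", x$drug, x$n_cases))
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
summary.dili_phenotype <- function(object, ...) {
  structure(list(phenotype = object), class = "summary.dili_phenotype")
}

#' @export
print.summary.dili_phenotype <- function(x, ...) {
  ph <- x$phenotype
  print(ph)
  fences <- t(vapply(ph$features, function(f) c(f$lower_fence, f$upper_fence),
                     numeric(2)))
  colnames(fences) <- c("lower_fence", "upper_fence")
  cat("\nOutlier fences (range +/- k*IQR, k =", ph$config$outlier_k, "):\n")
  print(round(fences, 3))
  cat(sprintf("\nQuantile convention: type %d\n", ph$config$quantile_type))
  interp <- unlist(lapply(ph$features, function(f) {
    if (length(f$interpolated)) paste0(f$feature, ":", paste(f$interpolated, collapse = ","))
  }))
  if (length(interp)) cat("Interpolated knots:", paste(interp, collapse = "  "), "\n")
  if (nzchar(ph$provenance)) cat("Provenance:", ph$provenance, "\n")
  invisible(x)
}

#' Extract the quantile knots of a fitted phenotype
#'
#' @param object a `dili_phenotype`.
#' @param ... unused.
#' @return A 3 x 9 numeric matrix (features x knots).
#' @export
coef.dili_phenotype <- function(object, ...) {
  t(vapply(object$features, function(f) f$knots, numeric(9)))
}

#' Plot the scoring bands of a fitted phenotype
#'
#' Draws, per feature, the nested percentile bands that drive point
#' allocation: the IQR core (20 points), the 15th-25th / 75th-85th shoulders
#' (10), the 10th-15th / 85th-90th shoulders (5) and the tails to the range
#' (0), with the outlier fences marked.
#'
#' @param x a `dili_phenotype`.
#' @param features which features to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dili_phenotype <- function(x, features = dc_features(), ...) {
  old <- graphics::par(mfrow = c(length(features), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  shades <- c(core = "grey30", near = "grey55", far = "grey75", tail = "grey90")
  for (f in features) {
    fp <- x$features[[f]]
    k <- fp$knots
    graphics::plot(NA, xlim = c(fp$lower_fence, fp$upper_fence), ylim = c(0, 1),
                   yaxt = "n", ylab = "", xlab = "", main = paste(x$drug, "-", f), ...)
    graphics::rect(k["min"], .3, k["max"], .7, col = shades["tail"], border = NA)
    graphics::rect(k["p10"], .3, k["p90"], .7, col = shades["far"], border = NA)
    graphics::rect(k["p15"], .3, k["p85"], .7, col = shades["near"], border = NA)
    graphics::rect(k["p25"], .3, k["p75"], .7, col = shades["core"], border = NA)
    graphics::abline(v = k["median"], col = "white", lwd = 2)
    graphics::abline(v = c(fp$lower_fence, fp$upper_fence), lty = 3)
  }
  invisible(x)
}

# --- structured-text (JSON) serialisation -----------------------------------

dc_schema_version <- "1.0"

#' Write and read phenotype files
#'
#' Phenotypes are serialised as JSON with a mandatory `schema_version` field,
#' the drug label, `n_cases`, provenance, the fitting configuration, and per
#' feature the 9 named knots, the fences, and any interpolated-knot flags.
#' The round trip is exact: `read_phenotype(write_phenotype(ph, f))` equals
#' `ph` field for field (numbers are written at full precision).
#'
#' @param phenotype a `dili_phenotype`.
#' @param path file path.
#' @param seed optional integer recorded in the file for provenance.
#' @return `read_phenotype()`: a `dili_phenotype`.
#' @export
write_phenotype <- function(phenotype, path, seed = NULL) {
  stopifnot(inherits(phenotype, "dili_phenotype"))
  payload <- list(
    schema_version = dc_schema_version,
    tool = paste0("dilicat ", as.character(utils::packageVersion("dilicat"))),
    config_hash = rlang::hash(phenotype$config),
    seed = seed,
    drug = phenotype$drug,
    n_cases = phenotype$n_cases,
    provenance = phenotype$provenance,
    config = phenotype$config,
    features = lapply(phenotype$features, function(f) {
      list(feature = f$feature, knots = as.list(f$knots),
           lower_fence = f$lower_fence, upper_fence = f$upper_fence,
           outlier_k = f$outlier_k, degenerate_eps = f$degenerate_eps,
           n = f$n, interpolated = f$interpolated)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) dc_validation_error(sprintf("phenotype file not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$schema_version)) {
    dc_validation_error(sprintf("%s: missing schema_version", path))
  }
  features <- lapply(payload$features, function(f) {
    feature_phenotype(
      knots = unlist(f$knots), n = f$n, feature = f$feature,
      outlier_k = f$outlier_k %||% 1.5,
      lower_fence = f$lower_fence, upper_fence = f$upper_fence,
      degenerate_eps = f$degenerate_eps %||% 0,
      interpolated = unlist(f$interpolated) %||% character()
    )
  })
  names(features) <- vapply(features, function(f) f$feature, character(1))
  features <- features[dc_features()]
  if (anyNA(names(features))) dc_validation_error(sprintf("%s: missing feature blocks", path))
  ns <- vapply(features, function(f) f$n, integer(1))
  if (length(unique(ns)) != 1) {
    dc_validation_error("feature blocks disagree on the number of source cases")
  }
  cfg <- payload$config %||% list()
  structure(
    list(drug = payload$drug, n_cases = as.integer(payload$n_cases),
         features = features,
         config = list(quantile_type = as.integer(cfg$quantile_type %||% 7),
                       outlier_k = cfg$outlier_k %||% 1.5,
                       degenerate_eps = cfg$degenerate_eps %||% 0,
                       round_latency = isTRUE(cfg$round_latency)),
         provenance = payload$provenance %||% ""),
    class = "dili_phenotype"
  )
}
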