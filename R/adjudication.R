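#' Configuration for the adjudication extensions
#'
#' A complete causality adjudication can stack two optional components on the
#' phenotype-based weighted score: points for competing causes and their lack
#' (spanning -25 to 25) and points for the drug's intrinsic hepatotoxicity
#' propensity (0 to 20). The printed method fixes only those ranges; the
#' category ladders shipped here are package defaults spanning them — a
#' five-level competing-cause ladder and a three-level propensity ladder —
#' and are meant to be replaced with locally agreed rubrics via the
#' `competing_rubric` / `hepatotoxicity_rubric` arguments.
#'
#' @param enable_competing_causes,enable_hepatotoxicity enable the respective
#'   component. Both default `FALSE`.
#' @param competing_rubric named integer vector mapping competing-cause
#'   assessment labels to points; all values must lie in \[-25, 25\].
#' @param hepatotoxicity_rubric named integer vector mapping propensity
#'   categories to points in \[0, 20\].
#' @param outlier_k,quantile_type scoring configuration carried alongside the
#'   rubrics so one config object describes a full run.
#' @return An object of class `dili_adjudication_config`.
#' @export
adjudication_config <- function(enable_competing_causes = FALSE,
                                enable_hepatotoxicity = FALSE,
                                competing_rubric = default_competing_rubric(),
                                hepatotoxicity_rubric = default_hepatotoxicity_rubric(),
                                outlier_k = 1.5, quantile_type = 7) {
  if (is.null(names(competing_rubric)) || any(!nzchar(names(competing_rubric)))) {
    dc_validation_error("`competing_rubric` must be a fully named vector")
  }
  if (is.null(names(hepatotoxicity_rubric)) || any(!nzchar(names(hepatotoxicity_rubric)))) {
    dc_validation_error("`hepatotoxicity_rubric` must be a fully named vector")
  }
  if (length(competing_rubric) < 2 || any(competing_rubric < -25 | competing_rubric > 25)) {
    dc_validation_error("`competing_rubric` points must lie in [-25, 25] with >= 2 categories")
  }
  if (length(hepatotoxicity_rubric) < 2 || any(hepatotoxicity_rubric < 0 | hepatotoxicity_rubric > 20)) {
    dc_validation_error("`hepatotoxicity_rubric` points must lie in [0, 20] with >= 2 categories")
  }
  structure(
    list(enable_competing_causes = isTRUE(enable_competing_causes),
         enable_hepatotoxicity = isTRUE(enable_hepatotoxicity),
         competing_rubric = competing_rubric,
         hepatotoxicity_rubric = hepatotoxicity_rubric,
         outlier_k = outlier_k,
         quantile_type = dc_check_quantile_type(quantile_type)),
    class = "dili_adjudication_config"
  )
}

#' @rdname adjudication_config
#' @export
default_competing_rubric <- function() {
  c("none identified, workup complete" = 25L,
    "none identified, workup incomplete" = 12L,
    "possible alternative cause" = 0L,
    "probable alternative cause" = -12L,
    "definite alternative cause" = -25L)
}

#' @rdname adjudication_config
#' @export
default_hepatotoxicity_rubric <- function() {
  c("low propensity" = 0L, "intermediate propensity" = 10L,
    "high propensity" = 20L)
}

#' Points for a competing-cause assessment
#'
#' @param label a category label present in the config's competing rubric.
#' @param config an [adjudication_config()].
#' @return Integer points in \[-25, 25\].
#' @export
competing_cause_points <- function(label, config = adjudication_config()) {
  stopifnot(inherits(config, "dili_adjudication_config"))
  if (!label %in% names(config$competing_rubric)) {
    dc_validation_error(sprintf(
      "unknown competing-cause label `%s`; valid labels: %s",
      label, paste(names(config$competing_rubric), collapse = "; ")))
  }
  unname(config$competing_rubric[[label]])
}

#' Points for a drug's hepatotoxicity propensity
#'
#' @param label a category label present in the config's hepatotoxicity rubric.
#' @param config an [adjudication_config()].
#' @return Integer points in \[0, 20\].
#' @export
hepatotoxicity_points <- function(label, config = adjudication_config()) {
  stopifnot(inherits(config, "dili_adjudication_config"))
  if (!label %in% names(config$hepatotoxicity_rubric)) {
    dc_validation_error(sprintf(
      "unknown hepatotoxicity label `%s`; valid labels: %s",
      label, paste(names(config$hepatotoxicity_rubric), collapse = "; ")))
  }
  unname(config$hepatotoxicity_rubric[[label]])
}

#' Combine the weighted score with enabled adjudication components
#'
#' @param case_score a one-row `dili_scores` object or a bare weighted total.
#' @param competing competing-cause points (integer in \[-25, 25\]) or `NULL`.
#' @param hepatotox hepatotoxicity points (integer in \[0, 20\]) or `NULL`.
#' @param config an [adjudication_config()]; a component is added only when
#'   its flag is enabled there.
#' @return The combined total, guaranteed within [theoretical_bounds()] for
#'   the active config.
#' @export
total_adjudication_score <- function(case_score, competing = NULL,
                                     hepatotox = NULL,
                                     config = adjudication_config()) {
  stopifnot(inherits(config, "dili_adjudication_config"))
  total <- if (inherits(case_score, "dili_scores")) {
    if (nrow(case_score) != 1) dc_validation_error("`case_score` must be a single case")
    case_score$weighted_total
  } else {
    dc_assert_finite(case_score, "`case_score`")
    case_score
  }
  if (total < -40 || total > 80) {
    dc_validation_error("weighted total out of range [-40, 80]")
  }
  if (config$enable_competing_causes) {
    if (is.null(competing)) dc_validation_error("competing-cause points required by config")
    if (competing < -25 || competing > 25) {
      dc_validation_error("competing-cause points out of range [-25, 25]")
    }
    total <- total + competing
  }
  if (config$enable_hepatotoxicity) {
    if (is.null(hepatotox)) dc_validation_error("hepatotoxicity points required by config")
    if (hepatotox < 0 || hepatotox > 20) {
      dc_validation_error("hepatotoxicity points out of range [0, 20]")
    }
    total <- total + hepatotox
  }
  total
}
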