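# Internal helpers shared across the package.

# Canonical feature labels, in tie-break priority order (latency first).
dc_features <- function() c("latency", "r_value", "ast_alt_ratio")

# Mapping from feature label to case-table column.
dc_feature_cols <- function() {
  c(latency = "latency_days", r_value = "r_value", ast_alt_ratio = "ast_alt_ratio")
}

# Probabilities of the 9-knot quantile profile.
dc_probs <- function() c(0, 0.10, 0.15, 0.25, 0.50, 0.75, 0.85, 0.90, 1)

dc_knot_names <- function() {
  c("min", "p10", "p15", "p25", "median", "p75", "p85", "p90", "max")
}

# Empirical quantiles under the package's two supported conventions.
# quantile_type 7 (linear interpolation at p*(n-1)+1, the base-R default) or 6.
dc_quantile <- function(x, probs, quantile_type = 7) {
  quantile_type <- dc_check_quantile_type(quantile_type)
  unname(stats::quantile(x, probs = probs, type = quantile_type, names = FALSE))
}

dc_check_quantile_type <- function(quantile_type) {
  if (!length(quantile_type) == 1 || !quantile_type %in% c(6, 7)) {
    dc_validation_error("`quantile_type` must be 6 or 7")
  }
  as.integer(quantile_type)
}

# Median under the same convention as the phenotype quantiles (types 6 and 7
# agree at p = 0.5, but route everything through one definition).
dc_median <- function(x, quantile_type = 7) {
  dc_quantile(x, 0.5, quantile_type = quantile_type)
}

# Validation failures carry a dedicated condition class so the CLI can map
# them to exit code 2.
dc_validation_error <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("dilicat_validation_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

dc_assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    dc_validation_error(sprintf("%s must be finite numeric", what))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
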