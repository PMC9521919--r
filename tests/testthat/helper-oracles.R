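# Fixture builders and independent brute-force oracles used across tests.

# Random case table with plausible clinical ranges.
rand_cases <- function(n, drug = "drugX") {
  data.frame(
    case_id = sprintf("%s_%02d", drug, seq_len(n)),
    drug = drug,
    latency_days = round(stats::runif(n, 1, 400), 1),
    r_value = round(stats::runif(n, 0, 30), 2),
    ast_alt_ratio = round(stats::runif(n, 0.1, 3), 2),
    stringsAsFactors = FALSE
  )
}

# Case table whose three features are all copies of one numeric vector
# (convenient for probing quantile behaviour of a single distribution).
cases_from_values <- function(values, drug = "drugX") {
  data.frame(drug = drug, latency_days = values, r_value = values,
             ast_alt_ratio = values, stringsAsFactors = FALSE)
}

# Brute-force band classifier: walks the explicit disjoint intervals of the
# point-allocation table (independent of the implementation's masking logic).
oracle_band_points <- function(value, fp) {
  k <- fp$knots
  iqr0 <- (k[["p75"]] - k[["p25"]]) == 0
  out <- if (iqr0) {
    FALSE  # degenerate profile, eps = 0: never an outlier
  } else {
    value < fp$lower_fence || value > fp$upper_fence
  }
  if (value < k[["min"]] || value > k[["max"]]) {
    return(if (out) -10L else -5L)
  }
  if (out) {
    # fence inside the observed range
    if (value >= k[["p25"]] && value <= k[["p75"]]) return(20L)
    return(-5L)
  }
  if (value >= k[["p25"]] && value <= k[["p75"]]) return(20L)
  if (value >= k[["p15"]] && value < k[["p25"]]) return(10L)
  if (value > k[["p75"]] && value <= k[["p85"]]) return(10L)
  if (value >= k[["p10"]] && value < k[["p15"]]) return(5L)
  if (value > k[["p85"]] && value <= k[["p90"]]) return(5L)
  0L
}

# Pair-counting Mann-Whitney oracle: U1 counts pairs where x beats y, half a
# point per cross-group tie; reported statistic is the smaller of U1 and U2.
oracle_u <- function(x, y) {
  U1 <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(U1, length(x) * length(y) - U1)
}

# Linear-by-linear association statistic computed from the 2 x K contingency
# table margins rather than per-case vectors.
oracle_trend <- function(scores_a, scores_b, bin_width = 5) {
  bins <- sort(unique(floor(c(scores_a, scores_b) / bin_width)))
  tab <- rbind(table(factor(floor(scores_a / bin_width), levels = bins)),
               table(factor(floor(scores_b / bin_width), levels = bins)))
  N <- sum(tab)
  u <- c(0, 1)
  v <- bins
  ri <- rowSums(tab); cj <- colSums(tab)
  ubar <- sum(ri * u) / N; vbar <- sum(cj * v) / N
  suv <- sum(tab * outer(u - ubar, v - vbar))
  su2 <- sum(ri * (u - ubar)^2); sv2 <- sum(cj * (v - vbar)^2)
  if (su2 == 0 || sv2 == 0) return(0)
  (N - 1) * suv^2 / (su2 * sv2)
}
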