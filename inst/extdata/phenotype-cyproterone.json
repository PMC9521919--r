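{
  "schema_version": "1.0",
  "tool": "dilicat 0.1.0",
  "config_hash": "95e1ac816aeb9cf29d87bc75f40e3805",
  "seed": null,
  "drug": "cyproterone",
  "n_cases": 22,
  "provenance": "Published case-series summary (median/IQR/range); interior percentiles interpolated.",
  "config": {
    "quantile_type": 7,
    "outlier_k": 1.5,
    "degenerate_eps": 0,
    "round_latency": false
  },
  "features": {
    "latency": {
      "feature": "latency",
      "knots": {
        "min": 33,
        "p10": 65.4,
        "p15": 81.6,
        "p25": 114,
        "median": 150,
        "p75": 240,
        "p85": 314,
        "p90": 351,
        "max": 425
      },
      "lower_fence": -156,
      "upper_fence": 614,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 22,
      "interpolated": ["p10", "p15", "p85", "p90"]
    },
    "r_value": {
      "feature": "r_value",
      "knots": {
        "min": 1,
        "p10": 4.12,
        "p15": 5.68,
        "p25": 8.8,
        "median": 12.4,
        "p75": 18,
        "p85": 22.8,
        "p90": 25.2,
        "max": 30
      },
      "lower_fence": -12.8,
      "upper_fence": 43.8,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 22,
      "interpolated": ["p10", "p15", "p85", "p90"]
    },
    "ast_alt_ratio": {
      "feature": "ast_alt_ratio",
      "knots": {
        "min": 0.2,
        "p10": 0.4,
        "p15": 0.5,
        "p25": 0.7,
        "median": 0.8,
        "p75": 1.2,
        "p85": 1.56,
        "p90": 1.74,
        "max": 2.1
      },
      "lower_fence": -0.55,
      "upper_fence": 2.85,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 22,
      "interpolated": ["p10", "p15", "p85", "p90"]
    }
  }
}
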