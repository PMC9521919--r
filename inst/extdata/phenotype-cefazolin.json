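{
  "schema_version": "1.0",
  "tool": "dilicat 0.1.0",
  "config_hash": "95e1ac816aeb9cf29d87bc75f40e3805",
  "seed": null,
  "drug": "cefazolin",
  "n_cases": 19,
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
        "min": 6,
        "p10": 10.8,
        "p15": 13.2,
        "p25": 18,
        "median": 20,
        "p75": 26,
        "p85": 27.2,
        "p90": 27.8,
        "max": 29
      },
      "lower_fence": -6,
      "upper_fence": 41,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 19,
      "interpolated": ["p10", "p15", "p85", "p90"]
    },
    "r_value": {
      "feature": "r_value",
      "knots": {
        "min": 0.5,
        "p10": 0.74,
        "p15": 0.86,
        "p25": 1.1,
        "median": 1.57,
        "p75": 3.4,
        "p85": 6.44,
        "p90": 7.96,
        "max": 11
      },
      "lower_fence": -2.95,
      "upper_fence": 14.45,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 19,
      "interpolated": ["p10", "p15", "p85", "p90"]
    },
    "ast_alt_ratio": {
      "feature": "ast_alt_ratio",
      "knots": {
        "min": 0.2,
        "p10": 0.28,
        "p15": 0.32,
        "p25": 0.4,
        "median": 0.4,
        "p75": 0.7,
        "p85": 0.9,
        "p90": 1,
        "max": 1.2
      },
      "lower_fence": -0.25,
      "upper_fence": 1.65,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 19,
      "interpolated": ["p10", "p15", "p85", "p90"]
    }
  }
}
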