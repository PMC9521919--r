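{
  "schema_version": "1.0",
  "tool": "dilicat 0.1.0",
  "config_hash": "95e1ac816aeb9cf29d87bc75f40e3805",
  "seed": null,
  "drug": "amx_cla",
  "n_cases": 35,
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
        "min": 4,
        "p10": 9.2,
        "p15": 11.8,
        "p25": 17,
        "median": 25.5,
        "p75": 38,
        "p85": 48,
        "p90": 53,
        "max": 63
      },
      "lower_fence": -27.5,
      "upper_fence": 94.5,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 35,
      "interpolated": ["p10", "p15", "p85", "p90"]
    },
    "r_value": {
      "feature": "r_value",
      "knots": {
        "min": 0.2,
        "p10": 0.36,
        "p15": 0.44,
        "p25": 0.6,
        "median": 1.44,
        "p75": 2.9,
        "p85": 7.34,
        "p90": 9.56,
        "max": 14
      },
      "lower_fence": -3.25,
      "upper_fence": 17.45,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 35,
      "interpolated": ["p10", "p15", "p85", "p90"]
    },
    "ast_alt_ratio": {
      "feature": "ast_alt_ratio",
      "knots": {
        "min": 0.2,
        "p10": 0.28,
        "p15": 0.32,
        "p25": 0.4,
        "median": 0.7,
        "p75": 0.9,
        "p85": 1.3,
        "p90": 1.5,
        "max": 1.9
      },
      "lower_fence": -0.55,
      "upper_fence": 2.65,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 35,
      "interpolated": ["p10", "p15", "p85", "p90"]
    }
  }
}
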