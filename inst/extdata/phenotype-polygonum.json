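{
  "schema_version": "1.0",
  "tool": "dilicat 0.1.0",
  "config_hash": "95e1ac816aeb9cf29d87bc75f40e3805",
  "seed": null,
  "drug": "polygonum",
  "n_cases": 18,
  "provenance": "Published case-series summary (median/IQR/range); interior percentiles interpolated. AST/ALT IQR printed descending (0.4-0.3) in the source: treated as inconsistent, IQR knots interpolated from median and range.",
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
        "min": 1,
        "p10": 3.4,
        "p15": 4.6,
        "p25": 7,
        "median": 20,
        "p75": 45,
        "p85": 75,
        "p90": 90,
        "max": 120
      },
      "lower_fence": -56,
      "upper_fence": 177,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 18,
      "interpolated": ["p10", "p15", "p85", "p90"]
    },
    "r_value": {
      "feature": "r_value",
      "knots": {
        "min": 2.8,
        "p10": 4.4,
        "p15": 5.2,
        "p25": 6.8,
        "median": 10.9,
        "p75": 14.3,
        "p85": 18.98,
        "p90": 21.32,
        "max": 26
      },
      "lower_fence": -8.45,
      "upper_fence": 37.25,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 18,
      "interpolated": ["p10", "p15", "p85", "p90"]
    },
    "ast_alt_ratio": {
      "feature": "ast_alt_ratio",
      "knots": {
        "min": 0.3,
        "p10": 0.34,
        "p15": 0.36,
        "p25": 0.4,
        "median": 0.5,
        "p75": 1.5,
        "p85": 1.9,
        "p90": 2.1,
        "max": 2.5
      },
      "lower_fence": -1.35,
      "upper_fence": 4.15,
      "outlier_k": 1.5,
      "degenerate_eps": 0,
      "n": 18,
      "interpolated": ["p10", "p15", "p25", "p75", "p85", "p90"]
    }
  }
}
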