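{
  "schema_version": "1.0",
  "roi_gate_ml_min_g": 0.39,
  "segmental_gate_ml_min_g": 0.44,
  "pv_recovery": 0.85,
  "dose_per_kg_MBq": 11.4,
  "input_window_s": 120,
  "tms_uptake_threshold_percent": 50,
  "literature_rows": [
    {"author": "Rivas", "year": 1976, "tracer": "microspheres", "mean_rmbf": null, "sd_rmbf": null, "upper_limit": 0.35, "n": "11 dogs", "method": "direct"},
    {"author": "Savage", "year": 1981, "tracer": "microspheres", "mean_rmbf": null, "sd_rmbf": null, "upper_limit": 0.25, "n": "11 pigs", "method": "direct"},
    {"author": "de Silva", "year": 1992, "tracer": "O-15 water", "mean_rmbf": 0.28, "sd_rmbf": 0.07, "upper_limit": 0.35, "n": "12 patients", "method": "roi"},
    {"author": "Czernin", "year": 1993, "tracer": "N-13 ammonia", "mean_rmbf": 0.32, "sd_rmbf": 0.12, "upper_limit": 0.44, "n": "13 patients", "method": "segmental"},
    {"author": "Bol", "year": 1993, "tracer": "microspheres, N-13, O-15 water", "mean_rmbf": null, "sd_rmbf": null, "upper_limit": 0.35, "n": "6 dogs", "method": "direct+roi"},
    {"author": "Gewirtz", "year": 1994, "tracer": "N-13 ammonia", "mean_rmbf": 0.27, "sd_rmbf": 0.17, "upper_limit": 0.44, "n": "22 infarct zones", "method": "segmental"},
    {"author": "Sun", "year": 1996, "tracer": "N-13 ammonia", "mean_rmbf": 0.28, "sd_rmbf": 0.09, "upper_limit": 0.37, "n": "16 patients", "method": "roi"},
    {"author": "Beanlands", "year": 1997, "tracer": "N-13 ammonia", "mean_rmbf": 0.30, "sd_rmbf": 0.06, "upper_limit": 0.36, "n": "8 patients", "method": "roi"},
    {"author": "Iida", "year": 2000, "tracer": "microspheres, O-15 water", "mean_rmbf": 0.19, "sd_rmbf": 0.14, "upper_limit": 0.33, "n": "12 dogs", "method": "roi"},
    {"author": "Zhang", "year": 2013, "tracer": "N-13 ammonia", "mean_rmbf": 0.32, "sd_rmbf": 0.09, "upper_limit": 0.41, "n": "36 regions", "method": "segmental"},
    {"author": "Wang", "year": 2020, "tracer": "N-13 ammonia", "mean_rmbf": 0.27, "sd_rmbf": 0.06, "upper_limit": 0.33, "n": "115 segments", "method": "segmental"},
    {"author": "Stewart", "year": 2022, "tracer": "Rb-82", "mean_rmbf": 0.32, "sd_rmbf": 0.07, "upper_limit": 0.39, "n": "16 patients", "method": "roi"}
  ]
}
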