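{
  "name": "brock_parsimonious",
  "description": "Parsimonious Brock University (PanCan) model for screening-detected nodules: sex, size, upper-lobe location, nodule type, nodule count, spiculation.",
  "citation": "McWilliams A, Tammemagi MC, Mayo JR, et al. Probability of cancer in pulmonary nodules detected on first screening CT. N Engl J Med. 2013;369(10):910-919.",
  "note": "Coefficients transcribed from the cited original (parsimonious model with spiculation); verify against the publication before any clinical-style use. Values are data, not code: replace this file to use a different calibration.",
  "intercept": -6.7892,
  "terms": [
    {"covariate": "sex", "coefficient": 0.6797, "transform": "indicator", "level": "female"},
    {"covariate": "diameter_mm", "coefficient": -5.3854, "transform": "brock_size", "offset": 1.58113883},
    {"covariate": "upper_lobe", "coefficient": 0.6581, "transform": "identity"},
    {"covariate": "nodule_type", "coefficient": 0.4771, "transform": "indicator", "level": "part_solid"},
    {"covariate": "nodule_type", "coefficient": -0.1102, "transform": "indicator", "level": "ggo"},
    {"covariate": "nodule_count", "coefficient": -0.0824, "transform": "center", "center": 4},
    {"covariate": "spiculation", "coefficient": 0.7729, "transform": "identity"}
  ]
}
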