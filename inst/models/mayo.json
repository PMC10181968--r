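{
  "name": "mayo",
  "description": "Mayo Clinic solitary pulmonary nodule malignancy model (incidentally detected nodules).",
  "citation": "Swensen SJ, Silverstein MD, Ilstrup DM, Schleck CD, Edell ES. The probability of malignancy in solitary pulmonary nodules. Application to small radiologically indeterminate nodules. Arch Intern Med. 1997;157(8):849-855.",
  "note": "Coefficients transcribed from the cited original publication.",
  "intercept": -6.8272,
  "terms": [
    {"covariate": "age_years", "coefficient": 0.0391, "transform": "identity"},
    {"covariate": "ever_smoker", "coefficient": 0.7917, "transform": "identity"},
    {"covariate": "prior_extrathoracic_cancer", "coefficient": 1.3388, "transform": "identity"},
    {"covariate": "diameter_mm", "coefficient": 0.1274, "transform": "identity"},
    {"covariate": "spiculation", "coefficient": 1.0407, "transform": "identity"},
    {"covariate": "upper_lobe", "coefficient": 0.7838, "transform": "identity"}
  ]
}
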