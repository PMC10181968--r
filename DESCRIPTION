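Package: qctlung
Title: Quantitative CT Lung Densitometry and Nodule Malignancy Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative computed-tomography (QCT) analysis of lung
    parenchyma for pulmonary-nodule malignancy risk estimation. Computes
    whole-lung and per-lobe densitometric parameters (mean lung density,
    emphysema index LAA-950, peripheral emphysema index, cluster-size
    classified emphysema, 15th-percentile density, bulla index,
    ground-glass and fibrosis indices, lung volume) with a 50/50
    central-peripheral zone partition, airway wall percentage and the
    Pi10 wall-thickness summary; compares the nodule-bearing lobe against
    the volume-weighted rest of the lung; and builds logistic-regression
    risk models with backward likelihood-ratio selection, integration of
    QCT covariates into the Mayo Clinic and parsimonious Brock models,
    and ROC/AUC evaluation with DeLong confidence intervals. Includes CT
    phantom and cohort simulators with analytic ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
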