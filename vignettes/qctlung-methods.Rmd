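---
title: "Quantitative CT lung analysis for nodule malignancy risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT lung analysis for nodule malignancy risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctlung)
```

## Scope

`qctlung` implements a quantitative-CT (QCT) analysis chain for patients
with an indeterminate pulmonary nodule: densitometric characterization of
the lung parenchyma the nodule sits in, comparison of the nodule-bearing
lobe against the rest of the lung, and integration of parenchymal metrics
into established clinical malignancy risk models. Because real cohorts of
this kind are rarely shareable, the package pairs every analysis stage
with a synthetic counterpart — CT phantoms with analytic ground truth and
cohort simulators with known generative structure — so the full chain is
testable end to end.

## Densitometric parameters

All parenchymal indices are computed over a voxel selection (whole lung,
one lobe, or any labelled region) of a HU volume with known voxel spacing:

* **MLD** (HU): mean attenuation over the region.
* **EI / LAA-950** (%): share of voxels strictly below −950 HU. The strict
  inequality is the dominant low-attenuation-area convention.
* **Perc15** (HU): 15th percentile of the region histogram, by linear
  interpolation between order statistics (quantile type 7). Deterministic
  and standard; lower values mean more emphysema.
* **EI~CC120~** (%): share of *region* voxels lying in emphysema clusters
  larger than 120 mm³ under 26-connectivity. Two conventions exist for the
  denominator (percent of lung vs percent of emphysema); the percent-of-lung
  reading is used here because typical reported magnitudes (medians two
  orders below EI) are only consistent with that reading. The threshold and
  connectivity are arguments.
* **BI** (%): a volume-based bulla surrogate — the emphysema mask is closed
  with a one-voxel 6-connectivity structuring element (so a bulla fragmented
  by thin septa counts once), clusters of the closed mask above 1000 mm³
  qualify, and the original emphysema voxels inside them are counted.
  Shape-based bulla detectors exist; this surrogate is deliberately simple,
  is documented as such, and its threshold is configurable.
* **GGOI** (%): voxels in \[−800, −700) HU; **FIBI** (%): voxels ≥ −700 HU.
  FIBI has no upper cap beyond region membership — the lung mask or label
  map is responsible for excluding soft tissue.
* **Lung volume** (mL): voxel count × voxel volume.

Cluster volumes always use the product of the per-axis spacings, so
anisotropic voxels are handled without special cases.

### Central/peripheral partition and pEI

The lung is split into 50% central and 50% peripheral zones per connected
lung component: the Euclidean distance of every lung voxel to the nearest
non-lung voxel is computed (exact separable lower-envelope transform,
anisotropy-aware), the component's median distance is the cutoff, and
voxels at or below the cutoff are peripheral. Ties at the cutoff go
peripheral, making the rule deterministic and the peripheral fraction at
least 50%. On blocky geometry the distance field is heavily tied, so the
peripheral fraction can exceed 50% by the tie mass at the cutoff (a 10³
cube yields 78.4%); on smooth anatomies ties are rare and the split is
close to exact.

The **peripheral emphysema index (pEI)** is the share of all emphysema
voxels that lie in the peripheral zone. An alternative reading — the LAA%
*within* the peripheral zone — exists, but reported pEI magnitudes
(~40–50% alongside EI ~1%) are only consistent with the share-of-emphysema
reading, which is what is implemented. When a region has no emphysema, pEI
is reported as missing, never as zero.

### Nodule handling

Nodule-labelled voxels are *included* in their bearing lobe by default,
mirroring densitometry pipelines that cannot segment and exclude the
nodule; `exclude_nodule = TRUE` removes them. On phantoms the difference
is measurable (the nodule adds soft-tissue voxels to the fibrosis band).

## Airway metrics

Airway tubes are measured slice-wise perpendicular to their principal
axis: lumen and wall areas from voxel counts, internal perimeter as the
marching-squares contour length of the lumen region, and wall thickness as
wall area over internal perimeter.

* **WP** (%): `100 · wall / (wall + lumen)` area, averaged without
  weighting over segments of generation ≥ 3 (trachea and main bronchi are
  excluded, as is common practice; the filter is configurable).
* **AWT-Pi10** (cm): ordinary least squares of wall thickness (mm) on
  internal perimeter (mm) across segments, evaluated at Pi = 10 mm. This
  regresses the *thickness itself*, not √wall-area: the conventional unit
  and magnitude of the reported summary (~0.2 cm) describe a thickness,
  and the two formulations cannot be reconciled numerically. The √WA
  convention is widespread elsewhere; the divergence is deliberate and
  documented here.

Measurements can come from labelled volumes or directly from the
documented per-segment CSV, so the statistical summaries are testable
without images.

## Lobe-specific analysis

The nodule-bearing lobe is compared with the pooled **rest of the lung**:
intensive metrics are pooled over non-bearing lobes by voxel-count
weighting (equivalently, by volume share), pEI by emphysema-count
weighting (it is a share of emphysema, not of volume), and volume is
summed. Pooling voxels rather than averaging per-lobe values is the
default because "weighted by volume share" recombines exactly: bearing
lobe plus pooled rest reproduce the whole-lung value to numerical
precision for every linear metric. Perc15 is not a linear functional; it
is recomputed from the pooled voxel histogram when the volumes are
available and otherwise approximated by a volume-weighted mean carrying an
explicit `perc15_approx` flag.

Across subjects the comparison uses the two-sided Wilcoxon signed-rank
test on paired differences: zeros dropped (classical treatment), midranks
for ties, the exact permutation distribution by generating-function
convolution for up to 25 nonzero pairs (valid under ties), and the
tie-corrected normal approximation beyond. An all-zero difference vector
reports p = 1 with a flag rather than an error.

## Cohort statistics and risk models

* **Group comparisons**: continuous variables by the two-sided
  Mann-Whitney U test — exact enumeration over all group assignments when
  both groups have ≤ 8 observations (valid under ties), otherwise the
  normal approximation with tie and continuity correction; categorical
  variables by Pearson chi-square without continuity correction.
  Descriptives are medians with IQRs, or counts with percentages.
* **Logistic regression**: maximum likelihood via IRLS, converging when
  the relative log-likelihood change falls below 1e-10 (cap 100
  iterations). Wald standard errors; odds ratios with 95% CIs as
  `exp(β ± 1.96·SE)`. Rank-deficient designs fail with the collinear
  columns named; separation fails with an explicit non-convergence error
  rather than returning a divergent fit.
* **Backward LR selection**: starting from candidates that pass a
  univariate screen (p < 0.05), the covariate whose removal has the
  largest likelihood-ratio p is dropped while that p ≥ `p_remove`
  (default 0.10, a common statistical-package default; ties break by
  covariate name order). The selection path is logged.
* **Clinical models**: the Mayo Clinic incidental-nodule model and the
  parsimonious Brock screening model are scored from cited, human-readable
  JSON constants files (`inst/models/`). The coefficients are data, not
  code: provenance is auditable and the files are replaceable. The
  covariate list and transforms (e.g. the Brock size term
  `(d/10)^(-1/2)` centred) are driven entirely by the file.
* **QCT integration**: the base model's predicted probability enters the
  extended model as its logit with a free recalibration coefficient, and
  the QCT covariates (MLD, pEI) are added. This makes base and extended
  properly nested, so the added value is a likelihood-ratio test with 2
  degrees of freedom. A fixed-offset mode is available behind a flag; the
  logit-covariate mode is the default because a free calibration slope is
  the weaker (safer) assumption when transporting a published model to a
  new cohort.
* **ROC/AUC**: the AUC is the tie-aware Mann-Whitney statistic; variance
  and 95% CI follow DeLong's placement decomposition, truncated to
  \[0, 1\]. AUCs are in-sample by design, matching the descriptive,
  all-available-data evaluation style this analysis accompanies —
  and therefore optimistic, which the reporting should state.

## Synthetic data: what it emulates, and what it does not

### Phantoms

A phantom is an air background, a soft-tissue body, five box lobes (three
right, two left, disjoint lungs) and rectangular compartments: emphysema
clusters (−980 HU), ground-glass (−750), fibrosis (−600), a nodule (−50),
plus voxelized annular airway tubes in a separate airway phantom. Boxes
rather than anatomical shapes are a deliberate choice: per-lobe arithmetic
needs labels, not anatomy, and box geometry keeps every expected value
analytic. Ground truth is computed from the painted geometry at paint time
(cluster sizes from placement, class counts from the painted HU), not by
re-measuring the image; the peripheral zone needed for the pEI ground
truth is computed by brute-force exact Euclidean minimization (a BLAS
outer-product route), independent of the pipeline's separable transform —
both are exact, so the cross-check is meaningful.

Optional Gaussian noise is clipped just inside each tissue class's HU
band, so class counts (and every percentage index) remain exactly known
while MLD shifts within the stated noise bound. Compartments are
rejection-placed at least 3 voxels apart so clusters stay distinct under
26-connectivity and one-voxel closing.

Phantoms default to 30×36×40 voxels at 1 mm spacing — small enough that a
validation run builds dozens of them in seconds, large enough that every
lobe can host multiple compartments. What phantoms do **not** emulate:
anatomical lobe shapes, vasculature, scanner kernels, or partial-volume
texture. Passing phantom tests therefore demonstrates arithmetical
correctness of the metrics, not robustness to clinical segmentation error.

### Cohort simulator

The simulator draws per-group QCT metrics from parametric families fitted
to (median, quartile) triplets: normal for MLD, Perc15, lung volume, WP
and AWT-Pi10; log-normal for the non-negative right-skewed emphysema
family (EI, EI~CC120~, BI, GGOI, FIBI); logit-normal for pEI/100 (a
bounded percentage). Scale parameters come from IQR/1.349 on the
transformed scale. The default calibration emulates the distributional
profile of a retrospective incidental-nodule cohort: benign/malignant EI
medians 0.7 vs 1.5%, pEI 40.1 vs 44.6%, MLD −766 vs −789 HU, FIBI 15.9 vs
13.9%, near-identical airway metrics. One quartile (the benign EI~CC120~
lower quartile, printed as 0.00) cannot parameterize a log-scale fit and
is replaced by a value one decade below the median. Clinical covariates
(age, sex, smoking including an explicit *unknown* category, family
history, nodule diameter, spiculation, location, type, count) follow the
same cohort profile; the prior-extrathoracic-cancer rate is not reported
there and is set to a plausible 10%/20%.

Two generation modes: *retrospective* (fixed group sizes, metrics drawn
per group) and *prospective* (covariates from the group-size-weighted
mixture, outcome from a user-specified logistic model — used for
coefficient-recovery and model-extension checks, where the generating
coefficients must be known).

### Problem sizes in the validation suite

The simulation-based checks use sizes chosen for statistical
resolution: Wald-coverage and selection simulations at n = 1000–2000 with
effects calibrated to Wald z ≈ 5 (β = 0.32 at n = 1000 for standard-normal
covariates and balanced outcome, from SE ≈ 1/√(n/4)); direction-of-effect
checks at 800 benign / 204 malignant, i.e. 4× the emulated study's size at
the same 80/20 mix. The 4× factor comes from an a-priori power
computation: at the calibrated group separations, the standardized
Mann-Whitney effect (pairwise exceedance probabilities ≈ 0.60–0.61) gives
only ~60–85% power at 200/51, while ≥ 97% per metric at 4×, so a ≥ 90%
detection rate across seeds is a fair bar for a correct implementation
rather than a coin flip.

## Numerical choices and degenerate inputs

* Percentile computation: quantile type 7 everywhere, including the exact
  pooled-histogram route (computed from value–count pairs).
* Distance transform: exact squared-distance lower envelope per axis with
  a large finite sentinel instead of infinity, so all-foreground scan
  lines stay NaN-free.
* Connected components: union-find with path compression in compiled
  code; 26-connectivity for emphysema clusters, 6-connectivity for
  segmentation and morphology. Test oracles use independent R
  implementations (queue-based flood fill, brute-force distances).
* Lung segmentation is a deliberately simple threshold surrogate
  (< −400 HU, border-connected air removed, small components dropped,
  enclosed holes filled) adequate for phantoms; clinical-grade lobe and
  airway segmentation is out of scope, and label maps are accepted as
  input instead.
* Empty regions, single-class outcomes, all-zero paired differences,
  zero-variance regressors, missing covariates under a strict policy, and
  non-overlapping label schemes all fail fast with named errors (or a
  flagged p = 1 where the convention is to report rather than fail).
* NIfTI pixdim is float32; spacings are rounded to 7 significant digits on
  read so metric spacings like 0.7 mm round-trip exactly.

## Known limitations

* The bulla index is a volume surrogate, not a shape detector; its
  agreement with shape-based implementations is untested by construction.
* The Pi10 thickness-on-perimeter convention differs from the √WA
  convention used by several airway packages; values are not comparable
  across conventions.
* Whether published multivariate odds ratios use per-unit or standardized
  covariates is often unstated; this package reports per-unit ORs.
* In-sample AUCs overstate transportable performance; an optional
  cross-validation flag is a natural extension but is deliberately not the
  default here, to match the descriptive analysis style.
* The packaged Mayo/Brock coefficient files are transcriptions from the
  cited originals and should be verified against those publications before
  any use beyond simulation.
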