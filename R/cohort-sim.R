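# Cohort simulator: benign/malignant groups with QCT metric distributions
# parameterized by (median, q1, q3) triplets and mapped onto parametric
# families (normal, log-normal, logit-normal). Defaults are calibrated to
# the distributional profile of a retrospective incidental-nodule cohort:
# modest emphysema burden shifted upward in the malignant group, fibrosis
# and ground-glass burden shifted downward, near-identical airway metrics.

#' Default QCT metric calibration table
#'
#' One row per metric per group with the quartiles that parameterize the
#' simulator: `family` is `normal` (location = median, scale = IQR/1.349),
#' `lognormal` (the same rule on the log scale) or `logitnormal`
#' (metric/100 on the logit scale, for bounded percentages).
#'
#' @return data.frame with columns metric, group, family, med, q1, q3.
#' @export
default_qct_calibration <- function() {
  tab <- rbind(
    c("mld_hu",         "normal",      -766, -796, -729,   -789, -802, -755),
    c("ei_pct",         "lognormal",    0.7,  0.2,  2.9,    1.5,  0.4,  4.5),
    c("pei_pct",        "logitnormal", 40.1, 32.6, 51.8,   44.6, 38.5, 53.9),
    c("ei_cc120_pct",   "lognormal",   0.03, 0.003, 0.36,  0.19, 0.01, 1.33),
    c("perc15_hu",      "normal",      -907, -923, -885,   -915, -930, -898),
    c("bi_pct",         "lognormal",   0.20, 0.05, 1.15,   0.63, 0.09, 2.38),
    c("ggoi_pct",       "lognormal",   12.5,  7.4, 19.6,    8.8,  6.2, 17.6),
    c("fibi_pct",       "lognormal",   15.9, 13.4, 23.0,   13.9, 12.7, 17.3),
    c("lung_volume_ml", "normal",      5443, 4678, 6654,   6233, 4962, 7460),
    c("wp_pct",         "normal",      46.4, 42.9, 51.6,   46.2, 42.0, 49.4),
    c("awt_pi10_cm",    "normal",      0.22, 0.17, 0.26,   0.21, 0.16, 0.25))
  out <- rbind(
    data.frame(metric = tab[, 1], group = "benign", family = tab[, 2],
               med = as.numeric(tab[, 3]), q1 = as.numeric(tab[, 4]),
               q3 = as.numeric(tab[, 5])),
    data.frame(metric = tab[, 1], group = "malignant", family = tab[, 2],
               med = as.numeric(tab[, 6]), q1 = as.numeric(tab[, 7]),
               q3 = as.numeric(tab[, 8])))
  rownames(out) <- NULL
  out
}

# (location, scale) of the transformed-normal family from quartiles;
# IQR of a normal = 1.349 sd
family_params <- function(family, med, q1, q3) {
  tr <- switch(family,
               normal = identity,
               lognormal = log,
               logitnormal = function(x) qlogis(x / 100))
  c(location = tr(med), scale = (tr(q3) - tr(q1)) / 1.349)
}

draw_metric <- function(n, family, loc, scale) {
  z <- rnorm(n, loc, scale)
  switch(family,
         normal = z,
         lognormal = exp(z),
         logitnormal = 100 * plogis(z))
}

#' Specify a simulated benign/malignant cohort
#'
#' Two generation modes. With `beta = NULL` (retrospective mode) group sizes
#' are fixed and each subject's QCT metrics are drawn from their group's
#' calibrated distribution. With true logistic coefficients `beta`
#' (prospective mode) covariates are drawn from the group-size-weighted
#' mixture distribution and the outcome follows
#' `Bernoulli(plogis(intercept + X beta))`.
#'
#' @param n_benign,n_malignant group sizes (>= 1).
#' @param calibration quartile table as from [default_qct_calibration()].
#' @param beta optional named numeric vector of true coefficients over
#'   cohort columns (e.g. `c(mld_hu = -0.01, pei_pct = 0.04)`).
#' @param intercept true intercept used with `beta`.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 200L, n_malignant = 51L,
                        calibration = default_qct_calibration(),
                        beta = NULL, intercept = 0, seed = 1L) {
  stopifnot(n_benign >= 1L, n_malignant >= 1L)
  for (i in seq_len(nrow(calibration))) {
    p <- family_params(calibration$family[i], calibration$med[i],
                       calibration$q1[i], calibration$q3[i])
    if (!is.finite(p["scale"]) || p["scale"] <= 0)
      stop("non-positive scale for metric ", calibration$metric[i])
  }
  if (!is.null(beta) && is.null(names(beta)))
    stop("beta must be a named vector")
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 calibration = calibration, beta = beta,
                 intercept = intercept, seed = as.integer(seed)),
            class = "cohort_spec")
}

# clinical covariate frequencies per group (benign, malignant):
# age and diameter as (location, scale); categoricals as probability vectors
clinical_defaults <- function() {
  list(
    age = list(benign = c(64, (73 - 55) / 1.349),
               malignant = c(67, (76 - 61) / 1.349)),
    sex_female = c(benign = 0.355, malignant = 0.412),
    smoking = list(benign = c(current = 0.110, former = 0.495,
                              never = 0.150, unknown = 0.245),
                   malignant = c(current = 0.137, former = 0.569,
                                 never = 0.176, unknown = 0.118)),
    family = list(benign = c(yes = 0.120, no = 0.755, unknown = 0.125),
                  malignant = c(yes = 0.039, no = 0.863, unknown = 0.098)),
    prior_cancer = c(benign = 0.10, malignant = 0.20),
    diameter = list(benign = c(7.9, 3.3), malignant = c(16.0, 11.8)),
    spiculation = c(benign = 0.225, malignant = 0.667),
    upper_lobe = c(benign = 0.375, malignant = 0.392),
    nodule_type = list(benign = c(solid = 0.895, part_solid = 0.075,
                                  ggo = 0.030),
                       malignant = c(solid = 0.843, part_solid = 0.137,
                                     ggo = 0.020)),
    emphysema_on_ct = c(benign = 0.22, malignant = 0.353)
  )
}

draw_clinical <- function(n, group) {
  cd <- clinical_defaults()
  ag <- cd$age[[group]]
  dm <- cd$diameter[[group]]
  # diameter: log-normal moment-matched to the group mean/SD, floored at 2 mm
  cv2 <- (dm[2] / dm[1])^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(dm[1]) - sdlog^2 / 2
  data.frame(
    age_years = pmin(pmax(round(rnorm(n, ag[1], ag[2])), 30), 95),
    sex = ifelse(runif(n) < cd$sex_female[[group]], "female", "male"),
    smoking_status = sample(names(cd$smoking[[group]]), n, TRUE,
                            cd$smoking[[group]]),
    family_lung_cancer = sample(names(cd$family[[group]]), n, TRUE,
                                cd$family[[group]]),
    prior_extrathoracic_cancer = rbinom(n, 1, cd$prior_cancer[[group]]),
    diameter_mm = round(pmax(rlnorm(n, meanlog, sdlog), 2), 1),
    spiculation = rbinom(n, 1, cd$spiculation[[group]]),
    upper_lobe = rbinom(n, 1, cd$upper_lobe[[group]]),
    nodule_type = sample(names(cd$nodule_type[[group]]), n, TRUE,
                         cd$nodule_type[[group]]),
    nodule_count = 1L + rpois(n, 0.3),
    emphysema_on_ct = rbinom(n, 1, cd$emphysema_on_ct[[group]]),
    stringsAsFactors = FALSE)
}

draw_qct <- function(n, group, calibration) {
  cols <- list()
  for (m in unique(calibration$metric)) {
    row <- calibration[calibration$metric == m & calibration$group == group, ]
    p <- family_params(row$family, row$med, row$q1, row$q3)
    cols[[m]] <- draw_metric(n, row$family, p["location"], p["scale"])
  }
  as.data.frame(cols)
}

#' Simulate a benign/malignant nodule cohort
#'
#' @param spec a [cohort_spec()].
#' @return validated cohort data.frame (schema of [read_cohort()]) with the
#'   generating truth attached as attributes `true_beta`, `true_intercept`,
#'   `seed`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  nb <- spec$n_benign; nm <- spec$n_malignant
  if (is.null(spec$beta)) {
    df <- rbind(cbind(draw_clinical(nb, "benign"),
                      draw_qct(nb, "benign", spec$calibration),
                      malignant = 0L),
                cbind(draw_clinical(nm, "malignant"),
                      draw_qct(nm, "malignant", spec$calibration),
                      malignant = 1L))
  } else {
    # mixture covariate population, outcome from the true logistic model
    n <- nb + nm
    w <- nb / n
    grp <- ifelse(runif(n) < w, "benign", "malignant")
    parts <- lapply(c("benign", "malignant"), function(g) {
      k <- sum(grp == g)
      if (k == 0) return(NULL)
      cbind(draw_clinical(k, g), draw_qct(k, g, spec$calibration))
    })
    df <- do.call(rbind, parts)
    eta <- rep(spec$intercept, n)
    for (v in names(spec$beta)) {
      if (!v %in% names(df)) stop("beta names a missing covariate: ", v)
      eta <- eta + spec$beta[[v]] * df[[v]]
    }
    pr <- plogis(eta)
    if (any(!is.finite(pr))) stop("degenerate outcome probability")
    df$malignant <- rbinom(n, 1, pr)
  }
  df <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  df <- validate_cohort(df)
  attr(df, "true_beta") <- spec$beta
  attr(df, "true_intercept") <- spec$intercept
  attr(df, "seed") <- spec$seed
  df
}
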