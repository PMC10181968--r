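# Lobe-specific analysis: pooling the non-bearing lobes into a
# volume-weighted "rest of lung" profile and paired signed-rank comparison
# of bearing lobe vs rest across subjects.

#' Pool per-lobe profiles into a rest-of-lung profile
#'
#' Combines all lobes except the nodule-bearing one. Intensive metrics are
#' pooled by voxel-count weighting (equivalently, by each lobe's share of
#' the pooled volume); the peripheral emphysema index is weighted by each
#' lobe's emphysema voxel count, since it is a share of emphysema; volume
#' and voxel counts are summed. The 15th percentile is not a linear
#' functional: when `ct` and `labels` are supplied it is recomputed exactly
#' from the pooled voxel histogram (as is the cluster-class index),
#' otherwise a volume-weighted mean is reported and flagged with attribute
#' `perc15_approx = TRUE`.
#'
#' @param profiles named list of lobe `qct_profile`s (names RUL..LLL).
#' @param bearing_lobe name or code of the nodule-bearing lobe.
#' @param ct,labels optional volumes for exact pooled recomputation.
#' @param nodule_lobe passed to [region_profile()] when recomputing.
#' @return a `qct_profile` for the pooled non-bearing lobes.
#' @export
rest_of_lung_profile <- function(profiles, bearing_lobe, ct = NULL,
                                 labels = NULL, nodule_lobe = NULL) {
  codes <- qct_labels()
  bname <- if (is.character(bearing_lobe)) bearing_lobe
           else names(codes)[match(bearing_lobe, codes)]
  if (!bname %in% names(profiles))
    stop("bearing lobe ", bname, " not among the profiles")
  rest <- profiles[setdiff(names(profiles), bname)]
  if (length(rest) < 1L) stop("subject has a single lobe; no rest of lung")

  if (!is.null(ct) && !is.null(labels)) {
    sel <- array(FALSE, dim(labels$labels))
    for (nm in names(rest)) {
      sel <- sel | labels$labels == codes[[nm]]
      if (!is.null(nodule_lobe)) {
        nl <- if (is.character(nodule_lobe)) codes[[nodule_lobe]]
              else nodule_lobe
        if (nl == codes[[nm]]) sel <- sel | labels$labels == codes[["nodule"]]
      }
    }
    lungsel <- resolve_region(labels, "lung", FALSE, nodule_lobe)
    zones <- partition_zones(lungsel, ct$spacing_mm)
    dm <- density_metrics(ct, sel)
    cm <- cluster_metrics(ct, sel)
    out <- structure(c(list(region_id = "rest_of_lung"), dm,
                       list(pei_pct = peripheral_emphysema_index(ct, sel, zones),
                            ei_cc120_pct = cm$ei_cc120_pct, bi_pct = cm$bi_pct,
                            wp_pct = NA_real_, awt_pi10_cm = NA_real_)),
                     class = "qct_profile")
    attr(out, "perc15_approx") <- FALSE
    return(out)
  }

  w <- vapply(rest, `[[`, numeric(1), "voxel_count")
  wm <- function(key) {
    v <- vapply(rest, `[[`, numeric(1), key)
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  # emphysema-count weights for the peripheral emphysema share
  we <- w * vapply(rest, `[[`, numeric(1), "ei_pct") / 100
  pei <- {
    v <- vapply(rest, `[[`, numeric(1), "pei_pct")
    ok <- !is.na(v) & we > 0
    if (!any(ok)) NA_real_ else sum(v[ok] * we[ok]) / sum(we[ok])
  }
  out <- structure(list(
    region_id = "rest_of_lung",
    mld_hu = wm("mld_hu"), perc15_hu = wm("perc15_hu"),
    ei_pct = wm("ei_pct"), ggoi_pct = wm("ggoi_pct"),
    fibi_pct = wm("fibi_pct"),
    volume_ml = sum(vapply(rest, `[[`, numeric(1), "volume_ml")),
    voxel_count = sum(w),
    pei_pct = pei, ei_cc120_pct = wm("ei_cc120_pct"), bi_pct = wm("bi_pct"),
    wp_pct = wm("wp_pct"), awt_pi10_cm = wm("awt_pi10_cm")),
    class = "qct_profile")
  attr(out, "perc15_approx") <- TRUE
  out
}

# exact null distribution of the signed-rank statistic for given |d| ranks
# (midranks allowed): generating-function convolution on a 2x grid
signed_rank_distribution <- function(ranks2) {
  # ranks2 = 2 * midranks, integers; returns probabilities over W2 = 0..sum
  probs <- c(1)
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) + shifted
  }
  probs / 2^length(ranks2)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (classical treatment); ranks of the absolute differences use midranks
#' for ties. For 25 or fewer nonzero differences the exact permutation
#' distribution of the statistic is computed by convolution over the
#' (possibly tied) ranks; otherwise a normal approximation with tie
#' correction is used. If every difference is zero the p value is reported
#' as 1 with `flag = "all_zero"`.
#'
#' @param x,y paired measurement vectors, or differences in `x` with
#'   `y = NULL`.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with statistic `W` (sum of positive-difference ranks),
#'   `p_value`, `n_used`, `method`, `flag`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W = 0, p_value = 1, n_used = 0L, method = "degenerate",
                flag = "all_zero"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    probs <- signed_rank_distribution(ranks2)
    w2 <- as.integer(round(2 * W))
    support <- seq_along(probs) - 1L
    p_lo <- sum(probs[support <= w2])
    p_hi <- sum(probs[support >= w2])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(W = W, p_value = p, n_used = n, method = method, flag = NA_character_)
}

#' Paired bearing-lobe vs rest-of-lung comparison across subjects
#'
#' @param bearing,rest per-subject metric values for the nodule-bearing
#'   lobe and the pooled rest of the lung.
#' @return list with medians and IQRs of both sides, the signed-rank
#'   p value, n, and any degeneracy flag.
#' @export
paired_lobar_test <- function(bearing, rest) {
  stopifnot(length(bearing) == length(rest))
  ok <- !is.na(bearing) & !is.na(rest)
  wt <- wilcoxon_signed_rank(bearing[ok], rest[ok])
  list(median_bearing = median(bearing[ok]),
       iqr_bearing = unname(quantile(bearing[ok], c(0.25, 0.75))),
       median_rest = median(rest[ok]),
       iqr_rest = unname(quantile(rest[ok], c(0.25, 0.75))),
       p_value = wt$p_value, n = sum(ok), n_nonzero = wt$n_used,
       method = wt$method, flag = wt$flag)
}
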