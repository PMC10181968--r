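# CT phantom generator. Phantoms are boxes-in-boxes: an air background, a
# soft-tissue body, five rectangular lobes (three right, two left, the two
# lungs disjoint), and rectangular tissue compartments painted inside lobes.
# All ground truth is derived from the painted geometry at paint time.

DENSITY_THRESHOLDS <- list(emphysema = -950, ggo_low = -800, ggo_high = -700)

hu_class <- function(hu) {
  # tissue class by the densitometric bands; "neutral" falls in no index
  ifelse(hu < -950, "emphysema",
         ifelse(hu < -800, "neutral",
                ifelse(hu < -700, "ggo", "fibrosis")))
}

# HU interval of the band containing `hu`, used to keep noise threshold-safe
hu_class_interval <- function(hu) {
  cls <- hu_class(hu)
  lo <- c(emphysema = -1100, neutral = -950, ggo = -800, fibrosis = -700)[cls]
  hi <- c(emphysema = -950, neutral = -800, ggo = -700, fibrosis = 3100)[cls]
  cbind(lo, hi)
}

#' Specify a CT phantom
#'
#' Defines the geometry and tissue composition of a synthetic chest CT:
#' five box-shaped lobes inside a soft-tissue body, plus emphysema clusters,
#' ground-glass and fibrosis compartments and a nodule, each a rectangular
#' box given as `list(lobe =, center =, size =, hu =)` with `center`/`size`
#' in voxel units (z, y, x).
#'
#' @param shape grid dimensions (z, y, x).
#' @param spacing_mm voxel spacing (z, y, x) in mm.
#' @param lobes named list of five `list(zlim, ylim, xlim)` voxel-index
#'   ranges, names RUL, RML, RLL, LUL, LLL; `NULL` for a default layout.
#' @param parenchyma_hu baseline lung HU (default -850, inside no index band).
#' @param body_hu,background_hu soft tissue and exterior air HU.
#' @param emphysema,ggo,fibrosis lists of box specs (HU defaults -980, -750,
#'   -600 respectively).
#' @param nodule single box spec or `NULL`; HU default -50.
#' @param noise_sd Gaussian HU noise, clipped so no voxel leaves its density
#'   band (0 disables; ground truth for class counts stays exact).
#' @param seed integer seed for the noise generator.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(30, 36, 40), spacing_mm = c(1, 1, 1),
                         lobes = NULL, parenchyma_hu = -850, body_hu = 20,
                         background_hu = -1000, emphysema = list(),
                         ggo = list(), fibrosis = list(), nodule = NULL,
                         noise_sd = 0, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L), all(spacing_mm > 0),
            noise_sd >= 0)
  if (is.null(lobes)) lobes <- default_lobe_layout(shape)
  stopifnot(identical(sort(names(lobes)),
                      sort(c("RUL", "RML", "RLL", "LUL", "LLL"))))
  fill_hu <- function(specs, hu) lapply(specs, function(s) {
    s$hu <- s$hu %||% hu; s
  })
  structure(list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
                 lobes = lobes, parenchyma_hu = parenchyma_hu,
                 body_hu = body_hu, background_hu = background_hu,
                 emphysema = fill_hu(emphysema, -980),
                 ggo = fill_hu(ggo, -750),
                 fibrosis = fill_hu(fibrosis, -600),
                 nodule = if (!is.null(nodule)) fill_hu(list(nodule), -50)[[1]],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom lobe layout
#'
#' Three right lobes stacked along z and two left lobes, the two lungs
#' separated by a soft-tissue mediastinum.
#'
#' @param shape grid dimensions (z, y, x).
#' @return named list of lobe voxel-index ranges for [phantom_spec()].
#' @export
default_lobe_layout <- function(shape) {
  zc <- 4:(shape[1] - 3)          # 1-voxel body margin inside the air shell
  yc <- 4:(shape[2] - 3)
  xmid <- floor(shape[3] / 2)
  xr <- 4:(xmid - 2)
  xl <- (xmid + 2):(shape[3] - 3)
  z3 <- split(zc, cut(seq_along(zc), 3, labels = FALSE))
  z2 <- split(zc, cut(seq_along(zc), 2, labels = FALSE))
  list(RUL = list(zlim = range(z3[[1]]), ylim = range(yc), xlim = range(xr)),
       RML = list(zlim = range(z3[[2]]), ylim = range(yc), xlim = range(xr)),
       RLL = list(zlim = range(z3[[3]]), ylim = range(yc), xlim = range(xr)),
       LUL = list(zlim = range(z2[[1]]), ylim = range(yc), xlim = range(xl)),
       LLL = list(zlim = range(z2[[2]]), ylim = range(yc), xlim = range(xl)))
}

box_indices <- function(center, size, shape) {
  lo <- round(center - (size - 1) / 2)
  hi <- lo + size - 1
  if (any(lo < 1L) || any(hi > shape)) stop("box outside grid")
  list(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
}

# exact quantile (type 7) from a value->count multiset, by cumulative counts
quantile_from_counts <- function(values, counts, p) {
  o <- order(values)
  values <- values[o]; counts <- counts[o]
  n <- sum(counts)
  if (n == 0L) return(NA_real_)
  h <- (n - 1) * p + 1
  k <- floor(h)
  cum <- cumsum(counts)
  vk <- values[which(cum >= k)[1]]
  if (h > k) {
    vk1 <- values[which(cum >= k + 1)[1]]
    vk + (h - k) * (vk1 - vk)
  } else vk
}

#' Generate a CT phantom with analytic ground truth
#'
#' Paints the phantom described by a [phantom_spec()] and returns the HU
#' volume, its label map and exact expected values for every densitometric
#' parameter, per lobe and for the whole lung. Ground truth is derived from
#' the painted geometry (voxel counts per placed compartment), not by
#' re-measuring the image; the peripheral zone needed for the peripheral
#' emphysema index is obtained with a brute-force exact Euclidean distance
#' computation, independent of the pipeline's separable transform.
#'
#' @param spec a [phantom_spec()].
#' @return list with `ct` ([ct_volume()]), `labels` ([label_volume()]) and
#'   `truth` (per-region expected metrics, cluster table, zone info).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  voxvol <- voxel_volume_mm3(spec$spacing_mm)
  hu <- array(spec$background_hu, dim = shape)
  labels <- array(0L, dim = shape)
  # 2-voxel air border, soft-tissue body inside
  hu[3:(shape[1] - 2), 3:(shape[2] - 2), 3:(shape[3] - 2)] <- spec$body_hu

  lobe_codes <- qct_labels()[c("RUL", "RML", "RLL", "LUL", "LLL")]
  for (nm in names(spec$lobes)) {
    lb <- spec$lobes[[nm]]
    zi <- lb$zlim[1]:lb$zlim[2]; yi <- lb$ylim[1]:lb$ylim[2]
    xi <- lb$xlim[1]:lb$xlim[2]
    if (any(labels[zi, yi, xi] != 0L)) stop("lobe boxes overlap at ", nm)
    labels[zi, yi, xi] <- lobe_codes[[nm]]
    hu[zi, yi, xi] <- spec$parenchyma_hu
  }

  paint_box <- function(b, what) {
    idx <- box_indices(b$center, b$size, shape)
    sub_lab <- labels[idx$z, idx$y, idx$x]
    sub_hu <- hu[idx$z, idx$y, idx$x]
    if (any(!sub_lab %in% 1:5) || any(sub_hu != spec$parenchyma_hu))
      stop("collision: ", what, " box at (",
           paste(b$center, collapse = ","), ") size (",
           paste(b$size, collapse = ","),
           ") overlaps non-parenchyma tissue or leaves the lung")
    lobe <- unique(as.vector(sub_lab))
    if (length(lobe) != 1L)
      stop("collision: ", what, " box spans multiple lobes")
    hu[idx$z, idx$y, idx$x] <<- b$hu
    list(lobe = lobe, n = prod(b$size))
  }

  clusters <- data.frame(cluster_id = integer(), lobe = integer(),
                         voxel_count = integer(), volume_mm3 = numeric(),
                         hu = numeric())
  for (i in seq_along(spec$emphysema)) {
    b <- spec$emphysema[[i]]
    if (b$hu >= DENSITY_THRESHOLDS$emphysema)
      stop("emphysema HU must be < -950")
    p <- paint_box(b, "emphysema")
    clusters <- rbind(clusters, data.frame(
      cluster_id = i, lobe = p$lobe, voxel_count = p$n,
      volume_mm3 = p$n * voxvol, hu = b$hu))
  }
  for (b in spec$ggo) {
    if (b$hu < -800 || b$hu >= -700) stop("GGO HU must lie in [-800, -700)")
    paint_box(b, "ggo")
  }
  for (b in spec$fibrosis) {
    if (b$hu < -700) stop("fibrosis HU must be >= -700")
    paint_box(b, "fibrosis")
  }
  nodule_lobe <- NA_integer_
  if (!is.null(spec$nodule)) {
    p <- paint_box(spec$nodule, "nodule")
    nodule_lobe <- p$lobe
    idx <- box_indices(spec$nodule$center, spec$nodule$size, shape)
    labels[idx$z, idx$y, idx$x] <- qct_labels()[["nodule"]]
  }

  base_hu <- hu
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    lung <- labels > 0L
    iv <- hu_class_interval(hu[lung])
    noisy <- hu[lung] + rnorm(sum(lung), 0, spec$noise_sd)
    # clip just inside the band so no voxel crosses a class threshold
    hu[lung] <- pmin(pmax(noisy, iv[, "lo"] + 0.01), iv[, "hi"] - 0.01)
  }

  truth <- phantom_truth(base_hu, labels, spec, clusters, nodule_lobe)
  list(ct = ct_volume(hu, spec$spacing_mm),
       labels = label_volume(labels, spec$spacing_mm),
       truth = truth)
}

# exact ground truth from the painted (noise-free) HU and labels
phantom_truth <- function(base_hu, labels, spec, clusters, nodule_lobe,
                          cc_threshold_mm3 = 120, bulla_threshold_mm3 = 1000) {
  voxvol <- voxel_volume_mm3(spec$spacing_mm)
  lung <- array(labels %in% c(1:5, 8L), dim(labels))
  # two lungs are disjoint by construction: components known analytically
  right <- array(labels %in% 1:3, dim(labels)) |
    (lung & labels == 8L & isTRUE(nodule_lobe %in% 1:3))
  left <- lung & !right
  peripheral <- array(FALSE, dim = dim(labels))
  cutoffs <- c(right = NA_real_, left = NA_real_)
  for (side in c("right", "left")) {
    comp <- if (side == "right") right else left
    if (!any(comp)) next
    d <- brute_force_edt(lung, comp, spec$spacing_mm)
    cutoffs[side] <- median(d)
    peripheral[comp][d <= cutoffs[side]] <- TRUE
  }

  emph <- lung & base_hu < -950
  big_cc <- clusters$cluster_id[clusters$volume_mm3 > cc_threshold_mm3]
  big_bulla <- clusters$cluster_id[clusters$volume_mm3 > bulla_threshold_mm3]

  region_truth <- function(sel, cl_sel) {
    n <- sum(sel)
    hu_vals <- base_hu[sel]
    tab <- table(hu_vals)
    vals <- as.numeric(names(tab)); cnts <- as.integer(tab)
    n_emph <- sum(hu_vals < -950)
    n_periph_emph <- sum(sel & emph & peripheral)
    cl <- clusters[clusters$cluster_id %in% cl_sel, , drop = FALSE]
    list(
      voxel_count = n,
      volume_ml = n * voxvol / 1000,
      mld_hu = sum(vals * cnts) / n,
      ei_pct = 100 * n_emph / n,
      pei_pct = if (n_emph == 0) NA_real_ else 100 * n_periph_emph / n_emph,
      ei_cc120_pct = 100 * sum(cl$voxel_count[cl$cluster_id %in% big_cc]) / n,
      bi_pct = 100 * sum(cl$voxel_count[cl$cluster_id %in% big_bulla]) / n,
      perc15_hu = quantile_from_counts(vals, cnts, 0.15),
      ggoi_pct = 100 * sum(hu_vals >= -800 & hu_vals < -700) / n,
      fibi_pct = 100 * sum(hu_vals >= -700) / n
    )
  }

  regions <- list(lung = region_truth(lung, clusters$cluster_id))
  for (nm in c("RUL", "RML", "RLL", "LUL", "LLL")) {
    code <- qct_labels()[[nm]]
    sel <- labels == code
    if (!is.na(nodule_lobe) && nodule_lobe == code) sel <- sel | labels == 8L
    regions[[nm]] <- region_truth(sel, clusters$cluster_id[clusters$lobe == code])
  }
  list(regions = regions, clusters = clusters, nodule_lobe = nodule_lobe,
       zone_cutoffs_mm = cutoffs,
       peripheral_fraction = sum(peripheral) / sum(lung),
       noise_sd = spec$noise_sd, seed = spec$seed)
}

# exact Euclidean distance from each voxel of `comp` to the nearest
# non-lung voxel, by direct minimization over boundary candidates (BLAS)
brute_force_edt <- function(lung, comp, spacing_mm) {
  boundary <- !lung & dilate6(lung)
  bidx <- which(boundary, arr.ind = TRUE)
  cidx <- which(comp, arr.ind = TRUE)
  B <- sweep(bidx, 2, spacing_mm, `*`)
  C <- sweep(cidx, 2, spacing_mm, `*`)
  b2 <- rowSums(B^2)
  # min_j ||c - b_j||^2 = |c|^2 + min_j (|b_j|^2 - 2 c.b_j), with the inner
  # minimum accumulated by column-wise pmin over boundary blocks
  best <- rep(Inf, nrow(C))
  block <- 512L
  for (s in seq(1L, nrow(B), by = block)) {
    e <- min(s + block - 1L, nrow(B))
    G <- tcrossprod(C, B[s:e, , drop = FALSE]) * -2
    for (j in seq_len(e - s + 1L))
      best <- pmin(best, G[, j] + b2[s + j - 1L])
  }
  sqrt(pmax(rowSums(C^2) + best, 0))
}

#' Randomized phantom specification
#'
#' Draws a phantom with randomized lobe sizes and randomly placed emphysema
#' clusters (sizes straddling the 120 mm\out{&#179;} cluster-class boundary, and
#' occasionally bulla-sized), ground-glass and fibrosis compartments and a
#' nodule. Placement is rejection-sampled so compartments stay at least
#' three voxels apart (clusters remain distinct under 26-connectivity and
#' one-voxel closing).
#'
#' @param seed integer seed.
#' @param shape grid dimensions (z, y, x).
#' @param noise_sd passed through to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, shape = c(30, 36, 40), noise_sd = 0) {
  set.seed(seed)
  lobes <- default_lobe_layout(shape)
  placed <- list()
  draw_box <- function(size) {
    # random lobe, random position, >= 3 voxels from previous boxes
    for (try in 1:200) {
      nm <- sample(names(lobes), 1)
      lb <- lobes[[nm]]
      lims <- rbind(lb$zlim, lb$ylim, lb$xlim)
      if (any(lims[, 2] - lims[, 1] + 1 < size + 2)) next
      lo <- mapply(function(a, b, s) a + sample.int(b - s + 2 - a, 1) - 1,
                   lims[, 1] + 1, lims[, 2] - 1, size)
      hi <- lo + size - 1
      ok <- all(vapply(placed, function(p)
        any(lo > p$hi + 3L | hi < p$lo - 3L), logical(1))) || !length(placed)
      if (ok) {
        placed[[length(placed) + 1L]] <<- list(lo = lo, hi = hi)
        return(list(center = (lo + hi) / 2, size = size))
      }
    }
    NULL
  }
  sizes <- list(c(5, 5, 5), c(4, 4, 4), c(6, 5, 4), c(3, 3, 3),
                c(11, 10, 10), c(2, 2, 2))   # 125, 64, 120, 27, 1100, 8 mm3
  n_emph <- sample(2:5, 1)
  emphysema <- list()
  for (s in sample(sizes, n_emph)) {
    b <- draw_box(s)
    if (!is.null(b)) emphysema[[length(emphysema) + 1L]] <- b
  }
  mk <- function(n, smin, smax) {
    out <- list()
    for (i in seq_len(n)) {
      b <- draw_box(sample(smin:smax, 3, replace = TRUE))
      if (!is.null(b)) out[[length(out) + 1L]] <- b
    }
    out
  }
  ggo <- mk(sample(1:2, 1), 3, 5)
  fibrosis <- mk(sample(1:2, 1), 3, 5)
  nodule <- draw_box(c(3, 3, 3))
  phantom_spec(shape = shape, emphysema = emphysema, ggo = ggo,
               fibrosis = fibrosis, nodule = nodule, noise_sd = noise_sd,
               seed = seed)
}
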