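# Airway cross-section measurement on labelled tubes, wall percentage and
# the Pi10 summary (modelled wall thickness at 10 mm internal perimeter).

# marching-squares length of the 0.5-isocontour of a binary 2-D mask,
# with x/y in physical mm
contour_length_mm <- function(mask2d, sp_y, sp_x) {
  z <- matrix(as.numeric(mask2d), nrow(mask2d), ncol(mask2d))
  # pad so contours close around regions touching the matrix edge
  zp <- matrix(0, nrow(z) + 2, ncol(z) + 2)
  zp[2:(nrow(z) + 1), 2:(ncol(z) + 1)] <- z
  cl <- contourLines(x = (seq_len(nrow(zp)) - 1) * sp_y,
                     y = (seq_len(ncol(zp)) - 1) * sp_x,
                     z = zp, levels = 0.5)
  sum(vapply(cl, function(cc)
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), numeric(1)))
}

#' Measure airway cross-sections from a labelled volume
#'
#' Tubes are the connected components of the lumen label. For each tube the
#' principal axis is taken from the spread of its lumen voxels and
#' cross-sections are evaluated slice-wise perpendicular to the closest
#' grid axis: lumen area and wall area from voxel counts, internal
#' perimeter as the marching-squares contour length of the lumen region,
#' wall thickness as wall area over internal perimeter. Per-segment values
#' are means over the tube's cross-sections. Wall voxels are assigned to
#' the tube whose lumen they surround; a tube with no wall voxels is
#' skipped with a warning.
#'
#' @param ct a [ct_volume()] (carried for interface symmetry; measurement
#'   uses the labels).
#' @param labels a [label_volume()] with lumen (6) and wall (7) voxels.
#' @param generations optional integer vector assigning an airway
#'   generation to each tube, in tube (component) order; default 3 for all.
#' @return data.frame with segment_id, generation, lumen_area_mm2,
#'   wall_area_mm2, internal_perimeter_mm, wall_thickness_mm (empty, with a
#'   warning, when no airway labels exist).
#' @export
measure_airways <- function(ct, labels, generations = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  lv <- labels$labels
  sp <- labels$spacing_mm
  lum <- lv == qct_labels()[["airway_lumen"]]
  wall <- lv == qct_labels()[["airway_wall"]]
  empty <- data.frame(segment_id = integer(), generation = integer(),
                      lumen_area_mm2 = numeric(), wall_area_mm2 = numeric(),
                      internal_perimeter_mm = numeric(),
                      wall_thickness_mm = numeric())
  if (!any(lum)) {
    warning("no airway labels found")
    return(empty)
  }
  comp <- label_components(lum, 26L)
  ncomp <- attr(comp, "n_labels")
  wcomp <- label_components(wall, 26L)
  if (!is.null(generations) && length(generations) != ncomp)
    stop("generations must have one entry per tube (", ncomp, ")")
  out <- empty
  for (k in seq_len(ncomp)) {
    sel <- comp == k
    idx <- which(sel, arr.ind = TRUE)
    # principal axis ~ grid axis with the largest physical extent
    ext <- apply(idx, 2, function(i) diff(range(i))) * sp
    ax <- which.max(ext)
    # wall component(s) adjacent to this lumen
    touch <- unique(wcomp[dilate6(sel) & wall])
    touch <- touch[touch > 0]
    if (!length(touch)) {
      warning("tube ", k, " has no wall label; skipped")
      next
    }
    wsel <- array(wcomp %in% touch, dim(wcomp))
    inplane <- setdiff(1:3, ax)
    area_vox <- prod(sp[inplane])
    slices <- sort(unique(idx[, ax]))
    la <- wa <- pm <- numeric(0)
    for (s in slices) {
      lsl <- slice_2d(sel, ax, s)
      wsl <- slice_2d(wsel, ax, s)
      if (!any(lsl)) next
      la <- c(la, sum(lsl) * area_vox)
      wa <- c(wa, sum(wsl) * area_vox)
      pm <- c(pm, contour_length_mm(lsl, sp[inplane[1]], sp[inplane[2]]))
    }
    gen <- if (is.null(generations)) 3L else generations[k]
    out <- rbind(out, data.frame(
      segment_id = k, generation = gen,
      lumen_area_mm2 = mean(la), wall_area_mm2 = mean(wa),
      internal_perimeter_mm = mean(pm),
      wall_thickness_mm = mean(wa / pm)))
  }
  out
}

slice_2d <- function(a, axis, i) {
  switch(axis, a[i, , ], a[, i, ], a[, , i])
}

#' Airway wall percentage
#'
#' Unweighted mean over eligible segments of
#' `100 * wall_area / (wall_area + lumen_area)`. Trachea and main bronchi
#' (generation below `min_generation`) are excluded.
#'
#' @param measurements data.frame as from [measure_airways()] (or the
#'   documented measurement CSV).
#' @param min_generation first eligible generation, default 3.
#' @return WP in percent.
#' @export
wall_percentage <- function(measurements, min_generation = 3L) {
  m <- measurements[measurements$generation >= min_generation, , drop = FALSE]
  if (nrow(m) == 0L) stop("no eligible segments after generation filter")
  mean(100 * m$wall_area_mm2 / (m$wall_area_mm2 + m$lumen_area_mm2))
}

#' Pi10: modelled wall thickness at 10 mm internal perimeter
#'
#' Ordinary least squares of wall thickness (mm) on internal perimeter (mm)
#' across segments; the regression line evaluated at 10 mm, in cm. (This
#' regresses the thickness itself, not the square root of wall area, so the
#' result is a thickness with the conventional ~0.2 cm magnitude.)
#'
#' @param measurements data.frame with `internal_perimeter_mm` and
#'   `wall_thickness_mm`.
#' @return predicted wall thickness at Pi = 10 mm, in cm. Attributes
#'   `intercept_mm` and `slope` carry the fitted line.
#' @export
awt_pi10 <- function(measurements) {
  x <- measurements$internal_perimeter_mm
  y <- measurements$wall_thickness_mm
  if (length(x) < 2L) stop("need at least 2 segments")
  if (any(x <= 0)) stop("internal perimeter must be positive")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in internal perimeter")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  icept <- mean(y) - slope * mean(x)
  structure((icept + slope * 10) / 10,   # mm -> cm
            intercept_mm = icept, slope = slope)
}
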