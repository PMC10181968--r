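# Straight-tube airway phantoms: annular cross-sections voxelized on a
# regular grid, with the analytic annulus geometry recorded alongside.

#' Specify one airway tube
#'
#' @param center_yx tube axis position in mm (y, x), axis along z.
#' @param lumen_radius_mm internal (lumen) radius, mm, > 0.
#' @param wall_thickness_mm wall thickness, mm, > 0.
#' @param generation airway generation (trachea = 0); default 3.
#' @param lumen_hu,wall_hu attenuation of lumen air and wall tissue.
#' @return list describing the tube.
#' @export
airway_tube <- function(center_yx, lumen_radius_mm, wall_thickness_mm,
                        generation = 3L, lumen_hu = -1000, wall_hu = -50) {
  stopifnot(lumen_radius_mm > 0, wall_thickness_mm > 0,
            length(center_yx) == 2L)
  list(center_yx = as.numeric(center_yx), lumen_radius_mm = lumen_radius_mm,
       wall_thickness_mm = wall_thickness_mm, generation = as.integer(generation),
       lumen_hu = lumen_hu, wall_hu = wall_hu)
}

#' Generate an airway phantom with analytic tube geometry
#'
#' Voxelizes straight tubes (axis along z) into a CT/label pair and records
#' the exact annulus geometry of each: lumen area \eqn{\pi r^2}, wall area
#' \eqn{\pi((r+t)^2 - r^2)}, internal perimeter \eqn{2\pi r}, wall thickness
#' \eqn{t}, plus the area/perimeter-consistent thickness
#' \eqn{t(2r+t)/(2r)} that a wall-area over perimeter estimator measures.
#'
#' @param tubes list of [airway_tube()] specs.
#' @param shape grid dimensions (z, y, x).
#' @param spacing_mm voxel spacing (z, y, x) in mm.
#' @param background_hu HU outside the tubes.
#' @return list with `ct`, `labels` and `geometry` (one row per tube).
#' @export
generate_airway_phantom <- function(tubes, shape = c(8, 60, 60),
                                    spacing_mm = c(1, 0.25, 0.25),
                                    background_hu = -900) {
  stopifnot(length(tubes) >= 1L)
  hu <- array(background_hu, dim = shape)
  labels <- array(0L, dim = shape)
  yc <- (seq_len(shape[2]) - 1) * spacing_mm[2]
  xc <- (seq_len(shape[3]) - 1) * spacing_mm[3]
  r2grid <- function(cy, cx) outer((yc - cy)^2, (xc - cx)^2, `+`)
  geom <- data.frame()
  for (i in seq_along(tubes)) {
    tb <- tubes[[i]]
    r <- tb$lumen_radius_mm; t <- tb$wall_thickness_mm
    outer_r <- r + t
    if (any(tb$center_yx - outer_r < 0) ||
        tb$center_yx[1] + outer_r > max(yc) ||
        tb$center_yx[2] + outer_r > max(xc))
      stop("tube ", i, " outside grid")
    d2 <- r2grid(tb$center_yx[1], tb$center_yx[2])
    lum <- d2 < r^2
    wall <- d2 >= r^2 & d2 < outer_r^2
    for (z in seq_len(shape[1])) {
      sl <- labels[z, , ]
      if (any(sl[lum | wall] != 0L)) stop("tube ", i, " overlaps another tube")
      sl[wall] <- qct_labels()[["airway_wall"]]
      sl[lum] <- qct_labels()[["airway_lumen"]]
      labels[z, , ] <- sl
      hz <- hu[z, , ]
      hz[wall] <- tb$wall_hu
      hz[lum] <- tb$lumen_hu
      hu[z, , ] <- hz
    }
    geom <- rbind(geom, data.frame(
      segment_id = i, generation = tb$generation,
      lumen_area_mm2 = pi * r^2,
      wall_area_mm2 = pi * (outer_r^2 - r^2),
      internal_perimeter_mm = 2 * pi * r,
      wall_thickness_mm = t,
      wall_thickness_ratio_mm = t * (2 * r + t) / (2 * r),
      wp_pct = 100 * (outer_r^2 - r^2) / outer_r^2))
  }
  list(ct = ct_volume(hu, spacing_mm),
       labels = label_volume(labels, spacing_mm),
       geometry = geom)
}
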