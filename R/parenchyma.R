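# Parenchymal densitometry: lung mask, central/peripheral partition and the
# density/cluster indices, computed for any voxel selection.

#' Threshold-based lung segmentation
#'
#' A deliberately simple surrogate for clinical lung segmentation, intended
#' for phantoms and other images where the lung is the internal
#' low-attenuation compartment: voxels below `threshold_hu` are labelled by
#' 6-connectivity, components touching the volume border (exterior air) are
#' discarded, small components are dropped, and internal holes (vessel-like
#' inclusions) up to `max_hole_voxels` are filled.
#'
#' @param ct a [ct_volume()].
#' @param threshold_hu air/tissue cut, default -400 HU.
#' @param min_fraction keep components at least this fraction of the
#'   largest interior component (both lungs survive, specks do not).
#' @param max_hole_voxels fill enclosed non-lung pockets up to this size.
#' @return logical lung mask (3-D array).
#' @export
segment_lungs <- function(ct, threshold_hu = -400, min_fraction = 0.05,
                          max_hole_voxels = 1000L) {
  stopifnot(inherits(ct, "ct_volume"))
  air <- ct$values < threshold_hu
  lab <- label_components(air, 6L)
  if (attr(lab, "n_labels") == 0L) stop("no lung found")
  d <- dim(lab)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  sizes <- tabulate(lab, nbins = attr(lab, "n_labels"))
  keep <- setdiff(which(sizes > 0), border)
  if (!length(keep)) stop("no lung found")
  keep <- keep[sizes[keep] >= min_fraction * max(sizes[keep])]
  mask <- array(lab %in% keep, d)
  # fill enclosed holes: background components not reaching the border
  bg <- label_components(!mask, 6L)
  bgborder <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                       bg[, , c(1, d[3])]))
  bgsizes <- tabulate(bg, nbins = attr(bg, "n_labels"))
  holes <- setdiff(which(bgsizes > 0 & bgsizes <= max_hole_voxels), bgborder)
  if (length(holes)) mask <- mask | array(bg %in% holes, d)
  mask
}

#' Partition a lung mask into 50% central / 50% peripheral zones
#'
#' Per connected lung component, the Euclidean distance (mm) of every lung
#' voxel to the nearest non-lung voxel is computed; the component's median
#' distance is the cutoff and voxels at or below it are peripheral. Ties at
#' the cutoff go peripheral, so the peripheral fraction is at least 50%.
#'
#' @param mask logical lung mask.
#' @param spacing_mm voxel spacing (z, y, x) in mm.
#' @return object of class `zone_partition`: `zones` (0 outside, 1 central,
#'   2 peripheral), `cutoff_mm` per component, per-zone voxel counts.
#' @export
partition_zones <- function(mask, spacing_mm) {
  if (!any(mask)) stop("empty lung mask")
  dist <- distance_to_boundary(mask, spacing_mm)
  comp <- label_components(mask, 26L)
  zones <- array(0L, dim(mask))
  ncomp <- attr(comp, "n_labels")
  cutoff <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    sel <- comp == k
    cutoff[k] <- median(dist[sel])
    zones[sel] <- ifelse(dist[sel] <= cutoff[k], 2L, 1L)
  }
  structure(list(zones = zones, cutoff_mm = cutoff,
                 n_central = sum(zones == 1L),
                 n_peripheral = sum(zones == 2L)),
            class = "zone_partition")
}

#' Densitometric indices of a region
#'
#' Mean lung density, 15th-percentile density (linear interpolation between
#' order statistics), emphysema index (share of voxels below the emphysema
#' threshold), ground-glass opacity index (share in \[-800, -700)),
#' fibrosis index (share at or above -700) and region volume.
#'
#' @param ct a [ct_volume()].
#' @param mask logical array selecting the region.
#' @param emphysema_hu,ggo_low_hu,ggo_high_hu band thresholds (defaults
#'   -950, -800, -700; the emphysema comparison is strict `<`).
#' @return list with mld_hu, perc15_hu, ei_pct, ggoi_pct, fibi_pct,
#'   volume_ml, voxel_count.
#' @export
density_metrics <- function(ct, mask, emphysema_hu = -950,
                            ggo_low_hu = -800, ggo_high_hu = -700) {
  stopifnot(inherits(ct, "ct_volume"))
  n <- sum(mask)
  if (n == 0L) stop("empty region mask")
  v <- ct$values[mask]
  list(mld_hu = sum(v) / n,
       perc15_hu = unname(quantile(v, 0.15, type = 7)),
       ei_pct = 100 * sum(v < emphysema_hu) / n,
       ggoi_pct = 100 * sum(v >= ggo_low_hu & v < ggo_high_hu) / n,
       fibi_pct = 100 * sum(v >= ggo_high_hu) / n,
       volume_ml = n * voxel_volume_mm3(ct$spacing_mm) / 1000,
       voxel_count = n)
}

#' Emphysema cluster table and cluster-class indices
#'
#' Labels emphysema voxels (HU below the threshold) by 26-connectivity.
#' The cluster-class index is the share of region voxels lying in clusters
#' larger than `cc_threshold_mm3`. The bulla index is a volume-based
#' surrogate for shape-based bulla detection: the emphysema mask undergoes
#' a one-voxel morphological closing, clusters of the closed mask larger
#' than `bulla_threshold_mm3` qualify, and the original emphysema voxels
#' inside them are counted.
#'
#' @param ct a [ct_volume()].
#' @param mask logical region mask.
#' @param emphysema_hu emphysema threshold, default -950 (strict `<`).
#' @param cc_threshold_mm3 cluster-class volume bound, default 120.
#' @param bulla_threshold_mm3 bulla volume bound, default 1000.
#' @param connectivity cluster connectivity, default 26.
#' @return list with `clusters` (data.frame: cluster_id, voxel_count,
#'   volume_mm3, centroid_z/y/x), `ei_cc120_pct`, `bi_pct`.
#' @export
cluster_metrics <- function(ct, mask, emphysema_hu = -950,
                            cc_threshold_mm3 = 120,
                            bulla_threshold_mm3 = 1000,
                            connectivity = 26L) {
  stopifnot(inherits(ct, "ct_volume"))
  n <- sum(mask)
  if (n == 0L) stop("empty region mask")
  voxvol <- voxel_volume_mm3(ct$spacing_mm)
  emph <- mask & ct$values < emphysema_hu
  lab <- label_components(emph, connectivity)
  nlab <- attr(lab, "n_labels")
  if (nlab == 0L) {
    clusters <- data.frame(cluster_id = integer(), voxel_count = integer(),
                           volume_mm3 = numeric(), centroid_z = numeric(),
                           centroid_y = numeric(), centroid_x = numeric())
    return(list(clusters = clusters, ei_cc120_pct = 0, bi_pct = 0))
  }
  idx <- which(emph, arr.ind = TRUE)
  labv <- lab[emph]
  counts <- tabulate(labv, nbins = nlab)
  clusters <- data.frame(
    cluster_id = seq_len(nlab), voxel_count = counts,
    volume_mm3 = counts * voxvol,
    centroid_z = as.vector(tapply(idx[, 1], labv, mean)),
    centroid_y = as.vector(tapply(idx[, 2], labv, mean)),
    centroid_x = as.vector(tapply(idx[, 3], labv, mean)))
  ei_cc120 <- 100 * sum(counts[counts * voxvol > cc_threshold_mm3]) / n

  closed <- close6(emph)
  clab <- label_components(closed, connectivity)
  csize <- tabulate(clab[closed], nbins = attr(clab, "n_labels"))
  big <- which(csize * voxvol > bulla_threshold_mm3)
  bi <- if (length(big)) 100 * sum(emph & array(clab %in% big, dim(clab))) / n
        else 0
  list(clusters = clusters, ei_cc120_pct = ei_cc120, bi_pct = bi)
}

#' Peripheral emphysema index
#'
#' Share of all emphysema voxels located in the peripheral lung zone.
#' Returns `NA` (an explicitly missing value, not 0) when the region
#' contains no emphysema.
#'
#' @param ct a [ct_volume()].
#' @param mask logical region mask.
#' @param zones a [partition_zones()] result on the same grid.
#' @param emphysema_hu threshold, default -950.
#' @return pEI in percent, or `NA_real_`.
#' @export
peripheral_emphysema_index <- function(ct, mask, zones, emphysema_hu = -950) {
  stopifnot(inherits(ct, "ct_volume"), inherits(zones, "zone_partition"))
  if (!identical(dim(zones$zones), dim(mask)))
    stop("zone partition and mask shapes differ")
  emph <- mask & ct$values < emphysema_hu
  tot <- sum(emph)
  if (tot == 0L) return(NA_real_)
  100 * sum(emph & zones$zones == 2L) / tot
}

resolve_region <- function(labels, region, exclude_nodule, nodule_lobe) {
  lv <- labels$labels
  codes <- qct_labels()
  if (identical(region, "lung")) {
    sel <- array(lv %in% 1:5, dim(lv))
    if (!exclude_nodule) sel <- sel | lv == codes[["nodule"]]
    return(sel)
  }
  code <- if (is.character(region)) codes[[region]] else as.integer(region)
  if (is.null(code) || !code %in% 1:5)
    stop("region must be 'lung', a lobe name or a lobe code 1-5")
  sel <- lv == code
  if (!exclude_nodule && !is.null(nodule_lobe)) {
    nl <- if (is.character(nodule_lobe)) codes[[nodule_lobe]] else nodule_lobe
    if (nl == code) sel <- sel | lv == codes[["nodule"]]
  }
  sel
}

#' Full QCT profile of a labelled region
#'
#' Assembles every parenchymal metric for the whole lung or one lobe.
#' Nodule voxels are included in their bearing lobe by default (mirroring
#' densitometry software that cannot exclude the nodule); set
#' `exclude_nodule = TRUE` to drop them.
#'
#' @param ct a [ct_volume()].
#' @param labels a [label_volume()] on the same grid.
#' @param region `"lung"`, a lobe name (RUL/RML/RLL/LUL/LLL) or code 1-5.
#' @param exclude_nodule drop nodule-labelled voxels (default FALSE).
#' @param nodule_lobe lobe containing the nodule (name or code); needed to
#'   include the nodule when profiling a single lobe.
#' @param zones optional precomputed [partition_zones()]; computed from the
#'   whole-lung mask when absent.
#' @param airway optional list with `wp_pct` and/or `awt_pi10_cm` to fill
#'   the airway fields.
#' @return object of class `qct_profile`.
#' @export
region_profile <- function(ct, labels, region = "lung",
                           exclude_nodule = FALSE, nodule_lobe = NULL,
                           zones = NULL, airway = NULL) {
  stopifnot(inherits(ct, "ct_volume"), inherits(labels, "label_volume"))
  if (!identical(dim(ct$values), dim(labels$labels)))
    stop("CT and label shapes differ")
  sel <- resolve_region(labels, region, exclude_nodule, nodule_lobe)
  if (!any(sel)) stop("empty region: ", region)
  if (is.null(zones)) {
    lungsel <- resolve_region(labels, "lung", exclude_nodule, nodule_lobe)
    zones <- partition_zones(lungsel, ct$spacing_mm)
  }
  dm <- density_metrics(ct, sel)
  cm <- cluster_metrics(ct, sel)
  structure(c(list(region_id = as.character(region)), dm,
              list(pei_pct = peripheral_emphysema_index(ct, sel, zones),
                   ei_cc120_pct = cm$ei_cc120_pct, bi_pct = cm$bi_pct,
                   wp_pct = airway$wp_pct %||% NA_real_,
                   awt_pi10_cm = airway$awt_pi10_cm %||% NA_real_)),
            class = "qct_profile")
}

#' @export
print.qct_profile <- function(x, ...) {
  cat("<qct_profile> region", x$region_id, "-", x$voxel_count, "voxels,",
      sprintf("%.1f mL\n", x$volume_ml))
  for (k in setdiff(profile_metric_keys(), "volume_ml"))
    cat(sprintf("  %-14s %s\n", k,
                ifelse(is.na(x[[k]]), "missing", sprintf("%.4g", x[[k]]))))
  invisible(x)
}

#' Profiles for every lobe present in a label volume
#'
#' @inheritParams region_profile
#' @return named list of `qct_profile`, one per lobe with voxels.
#' @export
lobe_profiles <- function(ct, labels, exclude_nodule = FALSE,
                          nodule_lobe = NULL) {
  lungsel <- resolve_region(labels, "lung", exclude_nodule, nodule_lobe)
  zones <- partition_zones(lungsel, ct$spacing_mm)
  out <- list()
  for (nm in c("RUL", "RML", "RLL", "LUL", "LLL")) {
    code <- qct_labels()[[nm]]
    if (!any(labels$labels == code)) next
    out[[nm]] <- region_profile(ct, labels, nm, exclude_nodule,
                                nodule_lobe, zones)
  }
  out
}
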