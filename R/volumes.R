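#' Label scheme for companion label volumes
#'
#' Integer codes used throughout the package: 0 background, 1-5 the five
#' lung lobes (RUL, RML, RLL, LUL, LLL), 6 airway lumen, 7 airway wall,
#' 8 nodule.
#'
#' @return named integer vector mapping region names to label codes.
#' @export
qct_labels <- function() {
  c(background = 0L, RUL = 1L, RML = 2L, RLL = 3L, LUL = 4L, LLL = 5L,
    airway_lumen = 6L, airway_wall = 7L, nodule = 8L)
}

HU_MIN <- -1100
HU_MAX <- 3100

#' CT volume container
#'
#' A 3-D grid of Hounsfield units with per-axis voxel spacing. Axis order is
#' (z, y, x): `dim(values)[1]` is the slice axis and `spacing_mm[1]` the
#' slice spacing.
#'
#' @param values 3-D numeric array of HU in \[-1100, 3100\].
#' @param spacing_mm three positive voxel spacings (z, y, x) in mm.
#' @param origin_mm physical position of the first voxel (default 0,0,0).
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("expected 3-D volume, got rank ", length(dim(values)) %||% 1L)
  if (any(dim(values) < 1L)) stop("each dimension must be >= 1")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be 3 strictly positive values")
  rng <- range(values)
  if (rng[1] < HU_MIN || rng[2] > HU_MAX)
    stop("HU values outside [", HU_MIN, ", ", HU_MAX, "]: range ",
         rng[1], "..", rng[2])
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' Label volume container
#'
#' Integer labels co-registered with a [ct_volume()]; codes follow
#' [qct_labels()].
#'
#' @param labels 3-D integer array.
#' @param spacing_mm voxel spacing (z, y, x) in mm.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_mm) {
  if (length(dim(labels)) != 3L) stop("expected 3-D label volume")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 strictly positive values")
  u <- unique(as.vector(labels))
  bad <- setdiff(u, qct_labels())
  if (length(bad))
    stop("labels outside the declared scheme: ", paste(bad, collapse = ", "))
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing (z,y,x) ", paste(x$spacing_mm, collapse = ", "),
      " mm, HU range [", min(x$values), ", ", max(x$values), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(x$labels)
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels; labels: ", paste(names(tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

voxel_volume_mm3 <- function(spacing_mm) prod(spacing_mm)

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header: ",
                                           conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stop("expected 3-D volume, got ", length(dim(img)), "-D image")
  pix <- attr(img, "pixdim")
  if (is.null(pix) || length(pix) < 3L)
    stop("NIfTI header missing field: pixdim")
  # NIfTI stores (x, y, z); normalize to the package's (z, y, x) order.
  # pixdim is float32 in the header: round to its 7 significant digits so
  # spacings like 0.7 mm survive the round-trip exactly
  list(values = aperm(array(as.numeric(img), dim(img)), c(3, 2, 1)),
       spacing_mm = signif(rev(as.numeric(pix[1:3])), 7))
}

#' Read a CT volume from NIfTI-1
#'
#' @param path path to a 3-D `.nii` / `.nii.gz` file.
#' @return a [ct_volume()]; axis order normalized to (z, y, x).
#' @export
read_ct_volume <- function(path) {
  a <- read_nifti_array(path)
  ct_volume(a$values, a$spacing_mm)
}

#' Read a label volume from NIfTI-1
#' @param path path to a 3-D NIfTI file of integer labels.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path) {
  a <- read_nifti_array(path)
  label_volume(round(a$values), a$spacing_mm)
}

write_nifti_array <- function(values, spacing_mm, path, datatype) {
  # header pixdim slot: (qfac, dx, dy, dz, dt, ...); data in (x, y, z)
  ref <- list(pixdim = c(-1, rev(spacing_mm), 0, 0, 0, 0))
  img <- RNifti::asNifti(aperm(values, c(3, 2, 1)), reference = ref,
                         datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a CT volume to NIfTI-1
#'
#' HU values are stored as int16 when they are whole numbers (the usual CT
#' case), otherwise as float.
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_ct_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  dt <- if (all(vol$values == round(vol$values))) "int16" else "float"
  write_nifti_array(vol$values, vol$spacing_mm, path, dt)
}

#' Write a label volume to NIfTI-1
#' @param vol a [label_volume()].
#' @param path output path.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  write_nifti_array(vol$labels, vol$spacing_mm, path, "int16")
}
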