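`%||%` <- function(a, b) if (is.null(a)) b else a

# shift a 3-D array by integer offsets, padding with `fill`
shift_array <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      dst[[k]] <- (1 + o):d[k]
      src[[k]] <- 1:(d[k] - o)
    } else {
      dst[[k]] <- 1:(d[k] + o)
      src[[k]] <- (1 - o):d[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-connectivity binary dilation / erosion (one voxel)
dilate6 <- function(mask) {
  out <- mask
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out | shift_array(mask, off, FALSE)
  out
}

erode6 <- function(mask) {
  out <- mask
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out & shift_array(mask, off, TRUE)
  out
}

# one-voxel morphological closing, 6-connectivity
close6 <- function(mask) erode6(dilate6(mask))

#' Label connected components of a 3-D mask
#'
#' Union-find labelling of the foreground voxels of a logical 3-D array,
#' under 6- (face) or 26- (face, edge, corner) connectivity.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 or 26.
#' @return integer array of the same shape; 0 for background, components
#'   numbered from 1. Attribute `n_labels` carries the component count.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lab <- .cc_label3d_cpp(as.vector(mask), dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_labels")
  dim(lab) <- dim(mask)
  attr(lab, "n_labels") <- n
  lab
}

#' Euclidean distance to background
#'
#' Exact Euclidean distance (mm) from every voxel to the nearest background
#' (`FALSE`) voxel centre, honouring anisotropic voxel spacing. Separable
#' lower-envelope distance transform.
#'
#' @param mask logical 3-D array (foreground `TRUE`).
#' @param spacing_mm per-axis voxel spacing, same axis order as `dim(mask)`.
#' @return numeric array of distances in mm (0 on background).
#' @export
distance_to_boundary <- function(mask, spacing_mm) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  d <- .edt3d_cpp(as.vector(mask), dim(mask), as.numeric(spacing_mm))
  dim(d) <- dim(mask)
  d
}
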