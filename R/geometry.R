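#' Image geometry of a 3D voxel lattice
#'
#' Bundles the lattice shape, the physical voxel spacing, and the 4x4 affine
#' that maps a 0-based voxel index \code{(i, j, k, 1)} to world coordinates
#' \code{(x, y, z, 1)} in millimeters. The world frame is RAS
#' (+x towards patient Right, +y Anterior, +z Superior) and the affine maps
#' voxel \emph{centers}.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, mm per voxel along each axis.
#'   Derived from the affine when omitted.
#' @param affine 4x4 numeric matrix. Defaults to a diagonal affine built from
#'   \code{spacing} with the origin at voxel (0, 0, 0).
#' @return An object of class \code{image_geometry}.
#' @export
image_geometry <- function(shape, spacing = NULL, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive integers", call. = FALSE)
  if (is.null(affine)) {
    if (is.null(spacing)) stop("supply `spacing` or `affine`", call. = FALSE)
    affine <- diag(c(spacing, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < 1e-12)
    stop("degenerate affine: determinant is (numerically) zero",
         call. = FALSE)
  derived <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (is.null(spacing)) {
    spacing <- derived
  } else {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(spacing <= 0))
      stop("`spacing` must be three positive reals", call. = FALSE)
    if (any(abs(spacing - derived) > 1e-6 * pmax(1, spacing)))
      stop("`spacing` disagrees with the affine column norms", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "image_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat("<image_geometry> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 6), collapse = " x "),
      " mm (RAS)\n", sep = "")
  invisible(x)
}

#' Binary segmentation mask on a 3D lattice
#'
#' @param voxels 3D array; any nonzero value is treated as foreground.
#' @param geometry an [image_geometry()].
#' @return An object of class \code{binary_mask} with elements
#'   \code{voxels} (integer 0/1 array), \code{geometry}, and
#'   \code{n_foreground}.
#' @export
binary_mask <- function(voxels, geometry) {
  if (!inherits(geometry, "image_geometry"))
    stop("`geometry` must be an image_geometry", call. = FALSE)
  if (length(dim(voxels)) != 3L)
    stop("mask voxel data must be a 3D array, got ",
         length(dim(voxels)), " dimensions", call. = FALSE)
  if (!identical(as.integer(dim(voxels)), geometry$shape))
    stop("voxel array dimensions do not match geometry shape", call. = FALSE)
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  m <- structure(list(voxels = v, geometry = geometry,
                      n_foreground = sum(v)),
                 class = "binary_mask")
  if (m$n_foreground > 0L && touches_boundary(m))
    warning("mask foreground touches the volume boundary; ",
            "distances beyond the field of view are unknowable",
            call. = FALSE)
  m
}

touches_boundary <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  any(v[1, , ] != 0L) || any(v[d[1], , ] != 0L) ||
    any(v[, 1, ] != 0L) || any(v[, d[2], ] != 0L) ||
    any(v[, , 1] != 0L) || any(v[, , d[3]] != 0L)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(x$geometry$shape, collapse = " x "),
      " voxels, ", x$n_foreground, " foreground (",
      signif(mask_volume_ml(x), 4), " ml)\n", sep = "")
  invisible(x)
}

# world coordinates (n x 3, mm) of 1-based voxel indices (n x 3)
voxel_to_world <- function(geometry, idx) {
  idx <- matrix(idx, ncol = 3L)
  h <- cbind(idx - 1, 1) %*% t(geometry$affine)
  h[, 1:3, drop = FALSE]
}

# length of the voxel diagonal in mm; the resolution of all voxel-center
# distance measurements
voxel_diagonal_mm <- function(geometry) sqrt(sum(geometry$spacing^2))

# 1-based indices (n x 3) of all foreground voxels
foreground_indices <- function(mask) {
  which(mask$voxels != 0L, arr.ind = TRUE)
}
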