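#' Mask volume in milliliters
#'
#' Foreground voxel count times the physical voxel volume
#' \code{|det(3x3 affine block)|} in mm^3, converted to ml.
#'
#' @param mask a [binary_mask()].
#' @return Volume in ml (0 for an empty mask).
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mask$n_foreground * abs(det(mask$geometry$affine[1:3, 1:3])) / 1000
}

#' Maximum 3D diameter of a mask
#'
#' The largest Euclidean world distance between any two surface voxel
#' centers — the tumor-size measure used for margin analysis. Computed
#' exactly over all surface-point pairs in compiled code; using voxel
#' centers under-reads the continuum diameter by at most one voxel
#' diagonal.
#'
#' @param mask a non-empty [binary_mask()].
#' @return Diameter in mm (0 for a single-voxel mask).
#' @export
max_diameter_mm <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$n_foreground == 0L)
    stop("degenerate mask: no foreground voxels", call. = FALSE)
  surf <- extract_surface(mask)
  .max_pairwise_dist_cpp(voxel_to_world(mask$geometry, surf))
}

#' Tumor or ice-ball morphometry
#'
#' @param mask a non-empty [binary_mask()].
#' @return List with \code{volume_ml} and \code{max_diameter_mm}.
#' @export
morphometry <- function(mask) {
  list(volume_ml = mask_volume_ml(mask),
       max_diameter_mm = max_diameter_mm(mask))
}
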