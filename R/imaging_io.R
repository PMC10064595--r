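#' Read a binary mask from a NIfTI file
#'
#' Loads a NIfTI-1/NIfTI-2 volume, reorients it to the RAS convention
#' (updating the affine consistently), and binarizes it: any nonzero voxel
#' becomes foreground.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop("mask file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  # tolerate trailing singleton dimensions (e.g. 3D stored as X x Y x Z x 1)
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)),
         " dimensions in ", path, call. = FALSE)
  dim(img) <- d
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0)
    RNifti::orientation(img) <- "RAS"   # reorient; no-op if already RAS
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (abs(det(aff)) < 1e-12)
    stop("degenerate affine in ", path, call. = FALSE)
  geom <- image_geometry(dim(img), affine = aff)
  binary_mask(array(as.integer(as.array(img) != 0), dim = dim(img)), geom)
}

#' Write a binary mask to a NIfTI file
#'
#' @param mask a [binary_mask()].
#' @param path output path (\code{.nii} or \code{.nii.gz}); the parent
#'   directory must exist and be writable.
#' @return Invisibly, \code{path}.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$geometry$spacing
  RNifti::qform(img) <- structure(mask$geometry$affine, code = 2L)
  RNifti::sform(img) <- structure(mask$geometry$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assert that two masks live on the same voxel grid
#'
#' Margin computation compares the two segmentations voxel by voxel, so
#' after co-registration and resampling both masks must share one lattice.
#'
#' @param a,b [binary_mask()] objects.
#' @param tol elementwise tolerance on the affines (mm).
#' @return Invisibly \code{TRUE}; errors on mismatch naming the offending
#'   field.
#' @export
assert_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(a$geometry$shape, b$geometry$shape))
    stop("grid mismatch in `shape`: ",
         paste(a$geometry$shape, collapse = "x"), " vs ",
         paste(b$geometry$shape, collapse = "x"), call. = FALSE)
  dev <- max(abs(a$geometry$affine - b$geometry$affine))
  if (dev > tol)
    stop("grid mismatch in `affine`: max deviation ", signif(dev, 4),
         " mm exceeds tol ", tol, call. = FALSE)
  invisible(TRUE)
}

#' Resample a mask onto a reference grid under a rigid transform
#'
#' Nearest-neighbor resampling: each voxel center of the reference lattice is
#' mapped back through the (inverse) rigid transform into the source volume
#' and takes the value of the nearest source voxel. Nearest-neighbor
#' interpolation is the only label-preserving choice for binary masks.
#' Reference voxels falling outside the source field of view become
#' background.
#'
#' @param mask source [binary_mask()].
#' @param reference target [image_geometry()].
#' @param transform a [rigid_transform()] mapping the source world frame into
#'   the reference world frame; identity by default.
#' @return A [binary_mask()] on the reference grid.
#' @export
resample_mask <- function(mask, reference, transform = rigid_identity()) {
  stopifnot(inherits(mask, "binary_mask"),
            inherits(reference, "image_geometry"))
  validate_rigid(transform, tol = 1e-6)
  # composite map: reference 0-based index -> world -> inverse transform
  # -> source world -> source 0-based index
  Tm <- transform_matrix(invert_transform(transform)) %*% reference$affine
  M <- solve(mask$geometry$affine) %*% Tm

  sh <- reference$shape
  idx <- as.matrix(expand.grid(i = 0:(sh[1] - 1L), j = 0:(sh[2] - 1L),
                               k = 0:(sh[3] - 1L)))
  src <- cbind(idx, 1) %*% t(M)
  si <- round(src[, 1]) + 1
  sj <- round(src[, 2]) + 1
  sk <- round(src[, 3]) + 1
  ss <- mask$geometry$shape
  ok <- si >= 1 & si <= ss[1] & sj >= 1 & sj <= ss[2] & sk >= 1 & sk <= ss[3]
  vals <- integer(nrow(idx))
  vals[ok] <- mask$voxels[cbind(si[ok], sj[ok], sk[ok])]
  suppressWarnings(binary_mask(array(vals, dim = sh), reference))
}
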