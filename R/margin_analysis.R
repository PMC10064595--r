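#' Signed Euclidean distance field of a binary mask
#'
#' For every voxel center the signed Euclidean distance, in physical
#' millimeters and aware of anisotropic voxel spacing, to the mask boundary:
#' positive inside the mask, negative outside. The boundary of a voxelized
#' mask lies between the face-exposed foreground shell (the surface voxels,
#' see [extract_surface()]) and the adjacent background shell, so the
#' distance from an interior point is estimated symmetrically as the mean of
#' its distance to the nearest surface voxel center and its distance to the
#' nearest background voxel center; for an exterior point the two sets
#' coincide (the nearest foreground voxel is always face-exposed) and the
#' magnitude is simply the distance to the nearest foreground voxel center.
#' All distances are between voxel centers — no sub-voxel mesh is fitted —
#' giving a boundary resolution of half a voxel diagonal.
#'
#' @param mask a [binary_mask()] with non-empty foreground \emph{and}
#'   background.
#' @return A list of class \code{signed_distance_field} with \code{values}
#'   (3D array, mm) and \code{geometry}.
#' @export
signed_distance_field <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n <- length(mask$voxels)
  if (mask$n_foreground == 0L)
    stop("degenerate mask: no foreground voxels", call. = FALSE)
  if (mask$n_foreground == n)
    stop("degenerate mask: no background voxels", call. = FALSE)
  fg <- mask$voxels != 0L
  sh <- mask$geometry$shape
  sp <- mask$geometry$spacing
  sites <- array(FALSE, dim = sh)
  sites[extract_surface(mask)] <- TRUE
  d_surf <- sqrt(.edt_sq_cpp(as.vector(sites), sh, sp))
  d_bg <- sqrt(.edt_sq_cpp(as.vector(!fg), sh, sp))
  vals <- ifelse(as.vector(fg), (d_surf + d_bg) / 2, -d_surf)
  structure(list(values = array(vals, dim = sh), geometry = mask$geometry),
            class = "signed_distance_field")
}

#' Surface voxels of a mask
#'
#' The surface is defined operationally as the foreground voxels with at
#' least one of their 6 face-neighbors in the background; voxels outside the
#' volume count as background.
#'
#' @param mask a non-empty [binary_mask()].
#' @return Integer n x 3 matrix of 1-based voxel indices.
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$n_foreground == 0L)
    stop("degenerate mask: no foreground voxels", call. = FALSE)
  v <- mask$voxels
  d <- dim(v)
  # pad with background so out-of-volume neighbors read as 0
  p <- array(0L, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  nb_min <- pmin(p[ix - 1, iy, iz], p[ix + 1, iy, iz],
                 p[ix, iy - 1, iz], p[ix, iy + 1, iz],
                 p[ix, iy, iz - 1], p[ix, iy, iz + 1])
  surf <- v == 1L & nb_min == 0L
  which(surf, arr.ind = TRUE)
}

#' Per-surface-point signed margin map
#'
#' For each tumor surface voxel, the signed distance from its center to the
#' ice-ball surface: positive when the point lies inside the ice ball,
#' negative when it protrudes. The minimum over the map is the minimal
#' treatment margin (MTM).
#'
#' @param tumor,ice [binary_mask()] objects on the same grid (see
#'   [assert_same_grid()]); resample first if needed.
#' @param ice_sdf optional precomputed [signed_distance_field()] of
#'   \code{ice}, to avoid recomputation across stages.
#' @return A list of class \code{margin_map} with \code{surface_idx}
#'   (1-based voxel indices), \code{surface_xyz_mm} (world coordinates), and
#'   \code{signed_margin_mm}.
#' @export
compute_margin_map <- function(tumor, ice, ice_sdf = NULL) {
  assert_same_grid(tumor, ice)
  if (ice$n_foreground == 0L)
    stop("degenerate mask: ice ball has no foreground voxels", call. = FALSE)
  if (is.null(ice_sdf)) ice_sdf <- signed_distance_field(ice)
  surf <- extract_surface(tumor)
  structure(list(
    surface_idx = surf,
    surface_xyz_mm = voxel_to_world(tumor$geometry, surf),
    signed_margin_mm = ice_sdf$values[surf],
    geometry = tumor$geometry), class = "margin_map")
}

octant_levels <- c("RAS", "RAI", "RPS", "RPI", "LAS", "LAI", "LPS", "LPI")

#' Octant partition of a tumor
#'
#' Assigns every tumor voxel to one of 8 anatomical octants formed by the
#' left-right, anterior-posterior, and cranio-caudal (superior-inferior)
#' patient axes through the tumor center of mass. Labels are three-letter
#' codes, e.g. \code{"RAS"} = Right-Anterior-Superior. A coordinate exactly
#' on a dividing plane goes to the positive (R/A/S) side.
#'
#' @param tumor a non-empty [binary_mask()].
#' @return A list with \code{octant} (factor, one level per tumor voxel in
#'   [foreground_indices()] order), \code{idx} (the voxel indices), and
#'   \code{center_mm} (the world-mm center of mass).
#' @export
octant_partition <- function(tumor) {
  stopifnot(inherits(tumor, "binary_mask"))
  if (tumor$n_foreground == 0L)
    stop("degenerate mask: no foreground voxels", call. = FALSE)
  idx <- foreground_indices(tumor)
  xyz <- voxel_to_world(tumor$geometry, idx)
  center <- colMeans(xyz)
  rel <- sweep(xyz, 2L, center)
  lab <- paste0(ifelse(rel[, 1] >= 0, "R", "L"),
                ifelse(rel[, 2] >= 0, "A", "P"),
                ifelse(rel[, 3] >= 0, "S", "I"))
  list(octant = factor(lab, levels = octant_levels), idx = idx,
       center_mm = center)
}

# octant labels for arbitrary world points given a center
octant_of_points <- function(xyz, center) {
  rel <- sweep(matrix(xyz, ncol = 3L), 2L, center)
  factor(paste0(ifelse(rel[, 1] >= 0, "R", "L"),
                ifelse(rel[, 2] >= 0, "A", "P"),
                ifelse(rel[, 3] >= 0, "S", "I")), levels = octant_levels)
}

#' Per-octant minimum signed margin
#'
#' @param map a [compute_margin_map()] result.
#' @param center_mm world center of mass of the tumor (the octant origin),
#'   e.g. from [octant_partition()].
#' @return Named numeric vector of length 8 (mm); \code{NA} for octants
#'   containing no surface point.
#' @export
octant_minima <- function(map, center_mm) {
  oct <- octant_of_points(map$surface_xyz_mm, center_mm)
  vapply(octant_levels, function(l) {
    v <- map$signed_margin_mm[oct == l]
    if (length(v) == 0L) NA_real_ else min(v)
  }, numeric(1))
}

#' Summarize the ablation margin of one case
#'
#' Reduces a margin map to the clinical headline quantities: the raw and
#' integer-mm minimal treatment margin (MTM; negative = incomplete
#' coverage), the location and octant of the minimum, per-octant minima, and
#' the three-class volumetric coverage of the tumor — \code{uncovered}
#' (tumor voxel outside the ice ball), \code{covered_insufficient} (inside,
#' but closer than \code{threshold_mm} to the ice surface), and
#' \code{covered_with_margin}.
#'
#' The integer margin uses round-half-away-from-zero; the raw value is kept
#' and used for all downstream statistics. Ties for the minimum resolve to
#' the first surface voxel in lexicographic index order.
#'
#' @param map a [compute_margin_map()] result.
#' @param tumor,ice the same-grid masks the map was computed from.
#' @param threshold_mm user-defined intended margin in mm (default 5, the
#'   ice-ball extension conventionally aimed for beyond the tumor border).
#' @param ice_sdf optional precomputed [signed_distance_field()] of
#'   \code{ice}.
#' @return A list of class \code{margin_summary}.
#' @export
summarize_margin <- function(map, tumor, ice, threshold_mm = 5,
                             ice_sdf = NULL) {
  stopifnot(inherits(map, "margin_map"))
  if (length(map$signed_margin_mm) == 0L)
    stop("empty margin map", call. = FALSE)
  if (threshold_mm < 0)
    stop("`threshold_mm` must be nonnegative", call. = FALSE)
  assert_same_grid(tumor, ice)
  if (is.null(ice_sdf)) ice_sdf <- signed_distance_field(ice)

  ord <- order(map$surface_idx[, 1], map$surface_idx[, 2],
               map$surface_idx[, 3])
  m <- map$signed_margin_mm
  imin <- ord[which.min(m[ord])]
  mtm_raw <- m[imin]

  part <- octant_partition(tumor)
  oct_min <- octant_minima(map, part$center_mm)
  argmin_oct <- as.character(octant_of_points(
    map$surface_xyz_mm[imin, , drop = FALSE], part$center_mm))

  tum_idx <- part$idx
  inside_ice <- ice$voxels[tum_idx] == 1L
  sdf_at_tumor <- ice_sdf$values[tum_idx]
  uncovered <- !inside_ice
  insufficient <- inside_ice & sdf_at_tumor < threshold_mm
  green <- inside_ice & !insufficient
  ntv <- nrow(tum_idx)
  cov <- c(covered_with_margin = sum(green) / ntv,
           covered_insufficient = sum(insufficient) / ntv,
           uncovered = sum(uncovered) / ntv)

  structure(list(
    mtm_raw_mm = mtm_raw,
    mtm_mm = as.integer(round_half_away(mtm_raw)),
    argmin_xyz_mm = as.numeric(map$surface_xyz_mm[imin, ]),
    argmin_octant = argmin_oct,
    octant_min_mm = oct_min,
    coverage_fractions = cov,
    threshold_mm = threshold_mm,
    margin_achieved = mtm_raw >= threshold_mm,
    n_surface_points = length(m),
    voxel_diagonal_mm = voxel_diagonal_mm(tumor$geometry)),
    class = "margin_summary")
}

#' @export
print.margin_summary <- function(x, ...) {
  cat("Minimal treatment margin: ", x$mtm_mm, " mm (raw ",
      signif(x$mtm_raw_mm, 4), " mm, resolution +/- ",
      signif(x$voxel_diagonal_mm / 2, 3), " mm)\n", sep = "")
  cat("  at (", paste(signif(x$argmin_xyz_mm, 4), collapse = ", "),
      ") mm, octant ", x$argmin_octant, "\n", sep = "")
  cat("  coverage: ",
      paste(sprintf("%s %.1f%%", names(x$coverage_fractions),
                    100 * x$coverage_fractions), collapse = ", "),
      " (threshold ", x$threshold_mm, " mm)\n", sep = "")
  invisible(x)
}

#' Export a margin map as a NIfTI scalar volume
#'
#' Writes the signed margin (mm) on tumor surface voxels and NaN elsewhere,
#' for overlay in external viewers.
#'
#' @param map a [compute_margin_map()] result.
#' @param path output NIfTI path.
#' @return Invisibly, \code{path}.
#' @export
write_margin_map <- function(map, path) {
  vol <- array(NaN, dim = map$geometry$shape)
  vol[map$surface_idx] <- map$signed_margin_mm
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- map$geometry$spacing
  RNifti::qform(img) <- structure(map$geometry$affine, code = 2L)
  RNifti::sform(img) <- structure(map$geometry$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
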