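#' Rigid transform in world millimeters
#'
#' A rotation plus translation acting on RAS world coordinates,
#' \code{y = R x + t}. Used to carry the pre-ablation segmentation into the
#' post-ablation frame (or vice versa) before resampling.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1, both
#'   within 1e-9).
#' @param translation numeric length-3 translation in mm.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  t <- structure(list(rotation = rotation, translation = translation),
                 class = "rigid_transform")
  validate_rigid(t)
  t
}

validate_rigid <- function(t, tol = 1e-9) {
  if (!inherits(t, "rigid_transform"))
    stop("expected a rigid_transform", call. = FALSE)
  R <- t$rotation
  if (!identical(dim(R), c(3L, 3L)) || length(t$translation) != 3L)
    stop("malformed rigid transform", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("transform rotation is not orthonormal (tol ", tol, ")",
         call. = FALSE)
  if (abs(det(R) - 1) > tol)
    stop("transform rotation is not proper (det != +1); ",
         "reflections are not rigid", call. = FALSE)
  invisible(TRUE)
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat("<rigid_transform> rotation ", signif(ang, 4), " deg, translation (",
      paste(signif(x$translation, 4), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

# 4x4 homogeneous matrix of a rigid transform
transform_matrix <- function(t) {
  rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
}

# rigid transform from a 4x4 homogeneous matrix
transform_from_matrix <- function(m, tol = 1e-6) {
  m <- unname(as.matrix(m))
  if (!identical(dim(m), c(4L, 4L)))
    stop("transform matrix must be 4x4", call. = FALSE)
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("matrix is not a proper rigid transform (tol ", tol, ")",
         call. = FALSE)
  # re-orthonormalize to machine precision so downstream invariants hold
  s <- svd(R)
  R <- s$u %*% t(s$v)
  rigid_transform(R, m[1:3, 4])
}

#' Apply a rigid transform to world points
#'
#' @param t a [rigid_transform()].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(t, points) {
  points <- matrix(points, ncol = 3L)
  sweep(points %*% t(t$rotation), 2L, t$translation, "+")
}

#' Compose two rigid transforms
#'
#' \code{compose_transforms(outer, inner)} applies \code{inner} first, then
#' \code{outer} — the way a manual adjustment is stacked on top of an initial
#' registration.
#'
#' @param outer,inner [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(outer, inner) {
  validate_rigid(outer); validate_rigid(inner)
  rigid_transform(outer$rotation %*% inner$rotation,
                  as.vector(outer$rotation %*% inner$translation) +
                    outer$translation)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  validate_rigid(t)
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% t$translation))
}

#' Paired anatomical landmarks
#'
#' World-mm coordinates of anatomical landmarks (cysts, renal cortex, local
#' vasculature, ...) identified in both the pre- and post-ablation frames,
#' used to fit the rigid co-registration.
#'
#' @param points n x 3 matrix of RAS world coordinates (mm).
#' @param labels optional character labels.
#' @return An object of class \code{landmark_set}.
#' @export
landmark_set <- function(points, labels = NULL) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (any(!is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("one label per landmark required", call. = FALSE)
  structure(list(points = points, labels = labels), class = "landmark_set")
}

#' Fit a rigid transform from paired landmarks
#'
#' Closed-form least-squares rigid registration (orthogonal Procrustes with
#' the scale fixed at 1): finds the rotation and translation minimizing the
#' (weighted) mean squared distance between transformed source landmarks and
#' their index-matched targets. If the optimal orthogonal matrix is a
#' reflection, the singular direction with the smallest singular value is
#' flipped to force a proper rotation.
#'
#' @param source,target [landmark_set()] objects with equal point counts
#'   (>= 3, not all collinear), corresponding by index.
#' @param weights optional nonnegative per-landmark weights (default
#'   uniform), letting users emphasize landmarks close to the treated area.
#' @return A [rigid_transform()] with attribute \code{rmsd_mm}, the
#'   post-fit root-mean-square landmark distance.
#' @export
fit_rigid <- function(source, target, weights = NULL) {
  stopifnot(inherits(source, "landmark_set"), inherits(target, "landmark_set"))
  X <- source$points; Y <- target$points
  n <- nrow(X)
  if (nrow(Y) != n)
    stop("landmark correspondence error: ", n, " source vs ", nrow(Y),
         " target points", call. = FALSE)
  if (n < 3L)
    stop("degenerate configuration: at least 3 landmark pairs required",
         call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("`weights` must be nonnegative with positive sum", call. = FALSE)
  w <- w / sum(w)

  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  # collinearity check: rank of the centered configuration
  sv <- svd(Xc * sqrt(w))$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("degenerate configuration: landmarks are collinear", call. = FALSE)

  H <- t(Xc * w) %*% Yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cy - as.vector(R %*% cx)
  fit <- rigid_transform(R, tr)
  resid <- apply_transform(fit, X) - Y
  attr(fit, "rmsd_mm") <- sqrt(sum(w * rowSums(resid^2)))
  fit
}

#' Read and write rigid transforms as JSON
#'
#' The on-disk format is a JSON object
#' \code{{"matrix": [16 reals, row-major 4x4], "frame": "RAS"}} with the
#' matrix acting on world millimeters.
#'
#' @param path file path.
#' @return \code{read_transform} returns a [rigid_transform()].
#' @export
read_transform <- function(path) {
  if (!file.exists(path))
    stop("transform file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$frame) && !identical(toupper(obj$frame), "RAS"))
    stop("transform frame must be RAS, got ", obj$frame, call. = FALSE)
  if (length(obj$matrix) != 16L)
    stop("transform `matrix` must hold 16 reals", call. = FALSE)
  transform_from_matrix(matrix(as.numeric(obj$matrix), 4L, 4L, byrow = TRUE))
}

#' @rdname read_transform
#' @param t a [rigid_transform()] to serialize.
#' @export
write_transform <- function(t, path) {
  validate_rigid(t)
  jsonlite::write_json(
    list(matrix = as.vector(t(transform_matrix(t))), frame = "RAS"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmarks from CSV
#'
#' Expects columns \code{label,x_mm,y_mm,z_mm} in RAS world millimeters.
#'
#' @param path CSV path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("landmark file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  landmark_set(cbind(df$x_mm, df$y_mm, df$z_mm), labels = df$label)
}
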