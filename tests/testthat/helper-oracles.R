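# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (all-pairs, O(n^2)) so they cannot share a defect with
# the transforms they check.

# all-pairs signed distance field over voxel centers, mm: outside the mask,
# minus the distance to the nearest foreground voxel center; inside, the
# mean of the distances to the nearest surface (face-exposed foreground)
# and nearest background voxel centers
brute_force_sdf <- function(mask) {
  d <- dim(mask$voxels)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- sweep(idx - 1, 2L, mask$geometry$spacing, "*")
  fg <- as.vector(mask$voxels) != 0L
  # naive face-exposure test, written independently of the package
  is_surface <- function(a) {
    if (!fg[a]) return(FALSE)
    v <- idx[a, ]
    for (ax in 1:3) for (s in c(-1, 1)) {
      nb <- v; nb[ax] <- nb[ax] + s
      if (nb[ax] < 1 || nb[ax] > d[ax]) return(TRUE)
      if (mask$voxels[nb[1], nb[2], nb[3]] == 0L) return(TRUE)
    }
    FALSE
  }
  surf <- vapply(seq_len(nrow(idx)), is_surface, logical(1))
  D <- as.matrix(stats::dist(xyz))
  out <- vapply(seq_len(nrow(idx)), function(a) {
    if (fg[a]) (min(D[a, surf]) + min(D[a, !fg])) / 2 else -min(D[a, fg])
  }, numeric(1))
  array(out, dim = d)
}

# random binary mask guaranteed non-degenerate (both classes present)
random_mask <- function(shape, spacing = c(1, 1, 1), p = 0.5, seed = 1L) {
  set.seed(seed)
  repeat {
    v <- array(as.integer(stats::runif(prod(shape)) < p), dim = shape)
    if (any(v == 1L) && any(v == 0L)) break
  }
  suppressWarnings(binary_mask(v, image_geometry(shape, spacing = spacing)))
}

# digital sphere mask on an isotropic or anisotropic grid; the shape is
# kept odd so the sphere center falls exactly on the central voxel
sphere_mask <- function(radius, spacing = c(1, 1, 1), pad = 4) {
  shape <- 2 * (ceiling(radius / spacing) + pad) + 1
  center <- (shape - 1) / 2 * spacing
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  xyz <- sweep(sweep(idx - 1, 2L, spacing, "*"), 2L, center)
  v <- array(as.integer(rowSums(xyz^2) <= radius^2), dim = shape)
  binary_mask(v, image_geometry(shape, spacing = spacing))
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_rigid <- function(seed, max_translation = 10) {
  set.seed(seed + 1000L)
  rigid_transform(random_rotation(seed),
                  stats::runif(3, -max_translation, max_translation))
}

# axis-aligned reference geometry covering the rigidly transformed extent of
# a source geometry, with `pad` voxels of clearance
covering_geometry <- function(geometry, transform, pad = 4) {
  sh <- geometry$shape
  corners <- as.matrix(expand.grid(c(1, sh[1]), c(1, sh[2]), c(1, sh[3])))
  w <- apply_transform(transform, voxel_to_world_t(geometry, corners))
  lo <- apply(w, 2, min) - pad * geometry$spacing
  hi <- apply(w, 2, max) + pad * geometry$spacing
  shape <- ceiling((hi - lo) / geometry$spacing) + 1
  aff <- diag(c(geometry$spacing, 1))
  aff[1:3, 4] <- lo
  image_geometry(shape, affine = aff)
}

# test-local duplicate of the package's voxel->world map (kept independent)
voxel_to_world_t <- function(geometry, idx) {
  h <- cbind(matrix(idx, ncol = 3) - 1, 1) %*% t(geometry$affine)
  h[, 1:3, drop = FALSE]
}

expect_rigid_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
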