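test_that("signed distance field matches the unit-lattice convention", {
  v <- array(0L, c(5, 5, 5)); v[3, 3, 3] <- 1L
  m <- binary_mask(v, image_geometry(c(5, 5, 5), c(1, 1, 1)))
  sdf <- signed_distance_field(m)
  # the lone voxel is its own surface; the boundary sits between it and its
  # background neighbors, half a spacing away
  expect_equal(sdf$values[3, 3, 3], 0.5)
  expect_equal(sdf$values[2, 3, 3], -1)      # face neighbors at -1 mm
  expect_equal(sdf$values[4, 3, 3], -1)
  expect_equal(sdf$values[3, 2, 3], -1)
  expect_equal(sdf$values[3, 3, 2], -1)
  expect_equal(sdf$values[2, 2, 3], -sqrt(2))
})

test_that("sphere center distance equals the radius within half a diagonal", {
  m <- sphere_mask(10)
  sdf <- signed_distance_field(m)
  c_idx <- (m$geometry$shape + 1) / 2
  expect_lt(abs(sdf$values[c_idx[1], c_idx[2], c_idx[3]] - 10),
            voxel_diagonal_mm(m$geometry) / 2 + 1e-12)
})

test_that("signed distance field matches brute force on random masks", {
  for (seed in 1:8) {
    sp <- if (seed %% 2 == 0) c(1, 1, 2.5) else c(1, 1, 1)
    m <- random_mask(c(5, 5, 5), spacing = sp, seed = seed)
    sdf <- signed_distance_field(m)
    expect_lt(max(abs(sdf$values - brute_force_sdf(m))), 1e-9)
  }
})

test_that("degenerate masks are rejected", {
  all_bg <- suppressWarnings(
    binary_mask(array(0L, c(3, 3, 3)), image_geometry(c(3, 3, 3), c(1, 1, 1))))
  expect_error(signed_distance_field(all_bg), "no foreground")
  all_fg <- suppressWarnings(
    binary_mask(array(1L, c(3, 3, 3)), image_geometry(c(3, 3, 3), c(1, 1, 1))))
  expect_error(signed_distance_field(all_fg), "no background")
  expect_error(extract_surface(all_bg), "no foreground")
})

test_that("extract_surface finds exactly the face-exposed voxels", {
  v <- array(0L, c(5, 5, 5)); v[3, 3, 3] <- 1L
  m <- binary_mask(v, image_geometry(c(5, 5, 5), c(1, 1, 1)))
  expect_equal(unname(extract_surface(m)), matrix(c(3, 3, 3), 1))

  v2 <- array(0L, c(5, 5, 5)); v2[2:4, 2:4, 2:4] <- 1L
  m2 <- binary_mask(v2, image_geometry(c(5, 5, 5), c(1, 1, 1)))
  expect_equal(nrow(extract_surface(m2)), 26)  # solid 3-cube minus center

  # digital surface voxel count of a sphere tracks the continuum area
  # 4*pi*r^2 to within the staircase factor (alignment-dependent, < 1.5x)
  s <- sphere_mask(10)
  n_surf <- nrow(extract_surface(s))
  expect_gt(n_surf, 4 * pi * 100 / 1.5)
  expect_lt(n_surf, 4 * pi * 100 * 1.5)
})

test_that("margin map on ice = tumor stays within the boundary band", {
  m <- sphere_mask(7)
  map <- compute_margin_map(m, m)
  d <- voxel_diagonal_mm(m$geometry)
  expect_true(all(abs(map$signed_margin_mm) <= d / 2 + 1e-12))
})

test_that("concentric spheres give a uniform +5 mm margin", {
  ph <- sphere_pair_phantom(10, 15, 0)
  map <- compute_margin_map(ph$tumor, ph$ice)
  d <- voxel_diagonal_mm(ph$tumor$geometry)
  expect_true(all(abs(map$signed_margin_mm - 5) <= d / 2 + 1e-12))
})

test_that("offset spheres give the analytic negative minimum margin", {
  ph <- sphere_pair_phantom(10, 15, 8)   # analytic MTM = 15 - 8 - 10 = -3
  map <- compute_margin_map(ph$tumor, ph$ice)
  d <- voxel_diagonal_mm(ph$tumor$geometry)
  expect_lt(abs(min(map$signed_margin_mm) - (-3)), d / 2 + 1e-12)
})

test_that("margin map agrees with brute force on random masks", {
  for (seed in 1:5) {
    tumor <- random_mask(c(5, 5, 5), p = 0.4, seed = seed)
    ice <- random_mask(c(5, 5, 5), p = 0.6, seed = seed + 100)
    map <- compute_margin_map(tumor, ice)
    bf <- brute_force_sdf(ice)[map$surface_idx]
    expect_lt(max(abs(map$signed_margin_mm - bf)), 1e-9)
  }
})

test_that("margin summary reports MTM, rounding, and coverage classes", {
  d <- sqrt(3)
  # wide margin: everything covered with margin
  ph <- sphere_pair_phantom(10, 16, 0)
  rep <- margin_analysis(ph$tumor, ph$ice, threshold_mm = 5)
  expect_identical(rep$summary$mtm_mm, 6L)
  expect_equal(rep$summary$coverage_fractions[["uncovered"]], 0)
  expect_gt(rep$summary$coverage_fractions[["covered_with_margin"]], 0.5)
  expect_equal(sum(rep$summary$coverage_fractions), 1)
  expect_true(rep$summary$margin_achieved)

  # covered but thin: green/yellow split, nothing uncovered
  ph2 <- sphere_pair_phantom(10, 13, 0)
  rep2 <- margin_analysis(ph2$tumor, ph2$ice, threshold_mm = 5)
  expect_identical(rep2$summary$mtm_mm, 3L)
  expect_equal(rep2$summary$coverage_fractions[["uncovered"]], 0)
  expect_gt(rep2$summary$coverage_fractions[["covered_insufficient"]], 0)
  expect_gt(rep2$summary$coverage_fractions[["covered_with_margin"]], 0)
  expect_false(rep2$summary$margin_achieved)

  # protrusion: negative MTM, uncovered volume, argmin on the protruding side
  ph3 <- sphere_pair_phantom(10, 15, 9, direction = c(1, 0, 0))
  rep3 <- margin_analysis(ph3$tumor, ph3$ice)
  expect_lt(rep3$summary$mtm_raw_mm, 0)
  expect_gt(rep3$summary$coverage_fractions[["uncovered"]], 0)
  # ice is offset towards +x, so the gap is on the Left side
  expect_match(rep3$summary$argmin_octant, "^L")
})

test_that("integer margin uses round-half-away-from-zero", {
  rha <- cryomargin:::round_half_away
  expect_equal(rha(c(2.5, -2.5, 2.4, -2.4, 0.5, -0.5, 0)),
               c(3, -3, 2, -2, 1, -1, 0))
})

test_that("negative MTM coincides with uncovered tumor volume", {
  for (off in c(0, 4, 7, 9, 12)) {
    ph <- sphere_pair_phantom(9, 13, off)
    rep <- margin_analysis(ph$tumor, ph$ice)
    uncovered <- rep$summary$coverage_fractions[["uncovered"]]
    expect_identical(rep$summary$mtm_raw_mm < 0, uncovered > 0)
  }
})

test_that("threshold must be nonnegative; zero threshold has no yellow", {
  ph <- sphere_pair_phantom(8, 11, 0)
  map <- compute_margin_map(ph$tumor, ph$ice)
  expect_error(summarize_margin(map, ph$tumor, ph$ice, threshold_mm = -1),
               "nonnegative")
  s0 <- summarize_margin(map, ph$tumor, ph$ice, threshold_mm = 0)
  expect_equal(s0$coverage_fractions[["covered_insufficient"]], 0)
})

test_that("octant partition splits a centered sphere evenly", {
  # center the sphere between voxels so no voxel sits on a dividing plane
  # (exact-plane voxels go to the positive side by the tie rule)
  sh <- c(26, 26, 26)
  idx <- as.matrix(expand.grid(seq_len(sh[1]), seq_len(sh[2]),
                               seq_len(sh[3])))
  rel <- sweep(idx - 1, 2L, (sh - 1) / 2)
  m <- binary_mask(array(as.integer(rowSums(rel^2) <= 81), dim = sh),
                   image_geometry(sh, c(1, 1, 1)))
  part <- octant_partition(m)
  counts <- table(part$octant)
  expect_identical(sum(counts), m$n_foreground)
  expect_lt(diff(range(counts)) / mean(counts), 0.05)
})

test_that("octant tie-breaking sends plane points to the positive side", {
  v <- array(0L, c(3, 3, 3)); v[2, 2, 2] <- 1L
  m <- binary_mask(v, image_geometry(c(3, 3, 3), c(1, 1, 1)))
  part <- octant_partition(m)
  expect_identical(as.character(part$octant), "RAS")

  v2 <- array(0L, c(4, 3, 3)); v2[2:3, 2, 2] <- 1L
  m2 <- binary_mask(v2, image_geometry(c(4, 3, 3), c(1, 1, 1)))
  labs <- sort(as.character(octant_partition(m2)$octant))
  expect_identical(labs, c("LAS", "RAS"))
})

test_that("octant minima are consistent with the global minimum", {
  ph <- sphere_pair_phantom(10, 14, 0)
  map <- compute_margin_map(ph$tumor, ph$ice)
  part <- octant_partition(ph$tumor)
  mins <- octant_minima(map, part$center_mm)
  d <- voxel_diagonal_mm(ph$tumor$geometry)
  expect_true(all(!is.na(mins)))
  expect_lt(diff(range(mins)), d / 2 + 1e-12)  # symmetric case
  expect_equal(min(mins), min(map$signed_margin_mm))

  # protrusion towards +x: global minimum in a Right octant
  ph2 <- sphere_pair_phantom(10, 14, 8, direction = c(-1, 0, 0))
  map2 <- compute_margin_map(ph2$tumor, ph2$ice)
  part2 <- octant_partition(ph2$tumor)
  mins2 <- octant_minima(map2, part2$center_mm)
  expect_true(names(which.min(mins2)) %in% c("RAS", "RAI", "RPS", "RPI"))
})

test_that("a tumor confined to one octant leaves seven minima undefined", {
  v <- array(0L, c(6, 6, 6)); v[2, 2, 2] <- 1L
  tumor <- binary_mask(v, image_geometry(c(6, 6, 6), c(1, 1, 1)))
  ice <- suppressWarnings(binary_mask(
    {a <- array(0L, c(6, 6, 6)); a[1:3, 1:3, 1:3] <- 1L; a},
    tumor$geometry))
  map <- compute_margin_map(tumor, ice)
  mins <- octant_minima(map, c(3, 3, 3))  # center away from the voxel
  expect_identical(sum(!is.na(mins)), 1L)
})

test_that("margin map NIfTI export stores signed mm on surface voxels", {
  dir <- withr::local_tempdir()
  ph <- sphere_pair_phantom(6, 9, 0)
  map <- compute_margin_map(ph$tumor, ph$ice)
  f <- file.path(dir, "map.nii.gz")
  write_margin_map(map, f)
  vol <- RNifti::readNifti(f)
  expect_equal(sum(!is.nan(as.array(vol))), nrow(map$surface_idx))
  expect_equal(as.array(vol)[map$surface_idx], map$signed_margin_mm,
               tolerance = 1e-6)
})

test_that("halving the voxel size tightens the sphere-phantom error", {
  err <- vapply(c(2, 1), function(h) {
    ph <- sphere_pair_phantom(10, 14, 5, spacing = rep(h, 3))
    rep <- margin_analysis(ph$tumor, ph$ice)
    abs(rep$summary$mtm_raw_mm - ph$truth$analytic_mtm_mm)
  }, numeric(1))
  # error bound is half the voxel diagonal, which halves with the spacing
  expect_lt(err[2], sqrt(3) / 2 + 1e-12)
  expect_lt(err[1], sqrt(3) + 1e-12)
})
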