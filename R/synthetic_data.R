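#' Specify a geometric tumor/ice-ball phantom
#'
#' An ellipsoidal "tumor" and an ellipsoidal "ice ball" rasterized on a
#' shared lattice, with analytic ground-truth margin, volumes, and diameter
#' so every pipeline stage can be validated without patient data.
#'
#' @param shape lattice shape (voxels per axis).
#' @param spacing voxel spacing, mm.
#' @param tumor,ice lists with \code{center} (world mm) and \code{semiaxes}
#'   (mm; a single value means a sphere).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape, spacing, tumor, ice) {
  geom <- image_geometry(shape, spacing = spacing)
  fix <- function(e) {
    if (length(e$semiaxes) == 1L) e$semiaxes <- rep(e$semiaxes, 3L)
    stopifnot(length(e$center) == 3L, length(e$semiaxes) == 3L,
              all(e$semiaxes > 0))
    e
  }
  tumor <- fix(tumor); ice <- fix(ice)
  lo <- voxel_to_world(geom, matrix(1, 1, 3))
  hi <- voxel_to_world(geom, matrix(shape, 1, 3))
  clear <- 2 * spacing
  for (e in list(tumor, ice)) {
    if (any(e$center - e$semiaxes < lo + clear) ||
        any(e$center + e$semiaxes > hi - clear))
      stop("ellipsoid exceeds the grid with < 2 voxels clearance",
           call. = FALSE)
  }
  structure(list(geometry = geom, tumor = tumor, ice = ice),
            class = "phantom_spec")
}

is_sphere <- function(e) diff(range(e$semiaxes)) == 0

# quasi-uniform directions on the unit sphere (Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# distance from world points (rows of q, relative to the ellipsoid center)
# to the surface of an ellipsoid with semi-axes b, by vectorized bisection
# on the Lagrange-multiplier equation; positive magnitude
dist_to_ellipsoid <- function(q, b) {
  q <- matrix(q, ncol = 3L)
  b2 <- b^2
  n <- nrow(q)
  # F(t) = sum_i b_i^2 q_i^2 / (b_i^2 + t)^2 - 1, strictly decreasing in t
  Fo <- function(t) {
    (b2[1] * q[, 1]^2) / (b2[1] + t)^2 +
    (b2[2] * q[, 2]^2) / (b2[2] + t)^2 +
    (b2[3] * q[, 3]^2) / (b2[3] + t)^2 - 1
  }
  lo <- rep(-min(b2) * (1 - 1e-12), n)
  hi <- sqrt(b2[1] * q[, 1]^2 + b2[2] * q[, 2]^2 + b2[3] * q[, 3]^2) + 1
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    pos <- Fo(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  t_star <- (lo + hi) / 2
  x <- cbind(b2[1] * q[, 1] / (b2[1] + t_star),
             b2[2] * q[, 2] / (b2[2] + t_star),
             b2[3] * q[, 3] / (b2[3] + t_star))
  sqrt(rowSums((x - q)^2))
}

# analytic (or brute-force) minimal margin between two ellipsoids:
# min over the tumor surface of the signed distance to the ice surface
phantom_truth_mtm <- function(tumor, ice, n_dirs = 100000) {
  if (is_sphere(tumor) && is_sphere(ice)) {
    off <- sqrt(sum((tumor$center - ice$center)^2))
    return(ice$semiaxes[1] - off - tumor$semiaxes[1])
  }
  d <- fibonacci_directions(n_dirs)
  # radius of the tumor ellipsoid along each direction
  r <- 1 / sqrt((d[, 1] / tumor$semiaxes[1])^2 +
                (d[, 2] / tumor$semiaxes[2])^2 +
                (d[, 3] / tumor$semiaxes[3])^2)
  p <- sweep(d * r, 2L, tumor$center, "+")
  q <- sweep(p, 2L, ice$center)
  inside <- (q[, 1] / ice$semiaxes[1])^2 + (q[, 2] / ice$semiaxes[2])^2 +
    (q[, 3] / ice$semiaxes[3])^2 < 1
  dist <- dist_to_ellipsoid(q, ice$semiaxes)
  min(ifelse(inside, dist, -dist))
}

#' Rasterize a phantom and compute its ground truth
#'
#' A voxel is foreground iff its center lies inside the ellipsoid. The
#' returned truth holds the analytic minimal treatment margin (closed form
#' \code{r_ice - |center offset| - r_tumor} for sphere pairs; dense surface
#' sampling with 1e5 directions for general ellipsoids), analytic volumes,
#' and the tumor's analytic maximum diameter.
#'
#' @param spec a [phantom_spec()].
#' @return List with \code{tumor} and \code{ice} ([binary_mask()]s sharing
#'   one geometry) and \code{truth}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- spec$geometry
  sh <- geom$shape
  idx <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                               k = seq_len(sh[3])))
  xyz <- voxel_to_world(geom, idx)
  inside <- function(e) {
    rel <- sweep(xyz, 2L, e$center)
    v <- (rel[, 1] / e$semiaxes[1])^2 + (rel[, 2] / e$semiaxes[2])^2 +
      (rel[, 3] / e$semiaxes[3])^2 <= 1
    array(as.integer(v), dim = sh)
  }
  tumor <- binary_mask(inside(spec$tumor), geom)
  ice <- binary_mask(inside(spec$ice), geom)
  truth <- list(
    analytic_mtm_mm = phantom_truth_mtm(spec$tumor, spec$ice),
    tumor_volume_ml = 4 / 3 * pi * prod(spec$tumor$semiaxes) / 1000,
    ice_volume_ml = 4 / 3 * pi * prod(spec$ice$semiaxes) / 1000,
    max_diameter_mm = 2 * max(spec$tumor$semiaxes))
  list(tumor = tumor, ice = ice, truth = truth)
}

#' Specify a synthetic cryoablation cohort
#'
#' Parametric generator reproducing the qualitative structure of a renal
#' cryoablation series: tumor diameters from a truncated normal, an inverse
#' size-margin relationship (larger tumors are harder to cover, so negative
#' margins concentrate above 3 cm), and local tumor progression driven by a
#' proportional-hazards model that is log-linear in the achieved margin,
#' with uniform administrative censoring. Defaults follow that clinical
#' picture: diameters 31.3 +/- 9.4 mm truncated to [16, 51]; margin
#' \code{9 - 2 * diameter_cm + N(0, 2.5)} mm; per-mm log-hazard -0.26;
#' follow-up censored uniformly on [1, 58] months. These are qualitative
#' study-condition settings, not estimates of any real cohort.
#'
#' @param n_cases number of treated tumors.
#' @param diameter_mean,diameter_sd,diameter_range truncated-normal tumor
#'   diameter distribution, mm.
#' @param margin_intercept,margin_slope,margin_sd margin model: intercept
#'   (mm), slope (mm per cm of diameter, entered as a positive decrement),
#'   and Gaussian noise sd (mm).
#' @param beta_mtm true log hazard ratio of progression per mm of margin.
#' @param baseline_hazard progression hazard per month at margin 0 mm.
#' @param censor_range administrative censoring window, months.
#' @param p_male,p_asa2,p_renal covariate frequencies (RENAL categories
#'   low/moderate/high).
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_cases = 32,
                        diameter_mean = 31.3, diameter_sd = 9.4,
                        diameter_range = c(16, 51),
                        margin_intercept = 9, margin_slope = 2,
                        margin_sd = 2.5,
                        beta_mtm = -0.26, baseline_hazard = 0.01,
                        censor_range = c(1, 58),
                        p_male = 0.666, p_asa2 = 0.566,
                        p_renal = c(low = 0.625, moderate = 0.344,
                                    high = 0.031)) {
  if (n_cases < 2) stop("`n_cases` must be >= 2", call. = FALSE)
  if (diameter_sd <= 0 || margin_sd < 0 || baseline_hazard <= 0)
    stop("invalid distribution parameters", call. = FALSE)
  if (diff(diameter_range) <= 0 || diff(censor_range) <= 0)
    stop("invalid range parameters", call. = FALSE)
  if (abs(sum(p_renal) - 1) > 0.01)
    stop("`p_renal` must sum to 1", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a cryoablation cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; generation is bit-reproducible given
#'   \code{(spec, seed)}.
#' @return A list with \code{records} (data frame of per-case records) and
#'   \code{truth} (the generator's parameters, including the true per-mm
#'   log hazard ratio and the true event-free survival function
#'   \code{truth$survival(record_index, t)}).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_cases
  diam <- rtruncnorm(n, spec$diameter_mean, spec$diameter_sd,
                     spec$diameter_range[1], spec$diameter_range[2])
  mtm_raw <- spec$margin_intercept - spec$margin_slope * diam / 10 +
    stats::rnorm(n, 0, spec$margin_sd)
  # morphometry derived from diameter: tumors as ~0.8 x 0.75 oblate
  # ellipsoids; ice balls as spheres extending ~7.5 mm beyond the tumor
  d_cm <- diam / 10
  tumor_vol <- pi / 6 * 0.8 * 0.75 * d_cm^3 * exp(stats::rnorm(n, 0, 0.15))
  ice_diam_cm <- d_cm + 1.5 + stats::rnorm(n, 0, 0.3)
  ice_vol <- pi / 6 * pmax(ice_diam_cm, d_cm + 0.5)^3
  n_probes <- pmin(4L, pmax(2L, as.integer(round(d_cm + stats::rnorm(n, 0,
                                                                     0.5)))))
  rate <- spec$baseline_hazard * exp(spec$beta_mtm * mtm_raw)
  t_event <- stats::rexp(n, rate)
  t_censor <- stats::runif(n, spec$censor_range[1], spec$censor_range[2])
  event <- t_event <= t_censor
  records <- data.frame(
    case_id = sprintf("case%03d", seq_len(n)),
    tumor_diameter_mm = diam,
    tumor_volume_ml = tumor_vol,
    iceball_volume_ml = ice_vol,
    n_probes = n_probes,
    mtm_raw_mm = mtm_raw,
    mtm_mm = as.integer(round_half_away(mtm_raw)),
    sex = ifelse(stats::runif(n) < spec$p_male, "male", "female"),
    asa = ifelse(stats::runif(n) < spec$p_asa2, "II", "III"),
    renal_category = sample(names(spec$p_renal), n, replace = TRUE,
                            prob = spec$p_renal),
    ltp = event,
    time_months = pmin(t_event, t_censor),
    event = event,
    stringsAsFactors = FALSE)
  truth <- list(beta_mtm = spec$beta_mtm,
                baseline_hazard = spec$baseline_hazard,
                margin_intercept = spec$margin_intercept,
                margin_slope = spec$margin_slope,
                seed = seed,
                survival = function(i, t)
                  exp(-rate[i] * t))
  list(records = records, truth = truth)
}

#' Validate a cohort data frame
#'
#' Checks the fixed per-case schema (see [simulate_cohort()]) and value
#' domains; used by the CSV reader and the reporting layer.
#'
#' @param records data frame of case records.
#' @return Invisibly, \code{records}; errors list offending rows.
#' @export
validate_cohort <- function(records) {
  need <- c("case_id", "tumor_diameter_mm", "mtm_raw_mm", "sex", "asa",
            "renal_category", "ltp", "time_months", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  records$ltp <- as.logical(records$ltp)
  records$event <- as.logical(records$event)
  bad <- which(records$time_months < 0 |
                 (records$event & !records$ltp) |
                 !(records$sex %in% c("male", "female")) |
                 !(records$asa %in% c("II", "III")) |
                 !(records$renal_category %in% c("low", "moderate", "high")))
  if (length(bad))
    stop("invalid case records in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

#' Read or write a cohort CSV
#'
#' One row per treated tumor with the fixed header of [simulate_cohort()]
#' records.
#'
#' @param path CSV path.
#' @return \code{read_cohort_csv} returns a validated data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
  df$ltp <- as.logical(df$ltp); df$event <- as.logical(df$event)
  df
}

#' @rdname read_cohort_csv
#' @param records cohort data frame.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Jittered landmark pairs for registration testing
#'
#' Source landmarks uniform in a 100 mm box centered on the origin (the
#' registration region of interest); targets are the rigidly transformed
#' sources plus isotropic Gaussian jitter.
#'
#' @param n number of landmarks (>= 3).
#' @param transform true [rigid_transform()].
#' @param sigma_mm jitter standard deviation.
#' @param seed integer seed.
#' @return List with \code{source} and \code{target} [landmark_set()]s.
#' @export
jittered_landmarks <- function(n, transform, sigma_mm = 0, seed = 1L) {
  if (n < 3L) stop("need at least 3 landmarks", call. = FALSE)
  set.seed(seed)
  src <- matrix(stats::runif(3 * n, -50, 50), ncol = 3L)
  tgt <- apply_transform(transform, src) +
    matrix(stats::rnorm(3 * n, 0, sigma_mm), ncol = 3L)
  list(source = landmark_set(src), target = landmark_set(tgt))
}
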