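#' Full margin analysis of one tumor/ice-ball pair
#'
#' The per-case pipeline: verify (or establish, by resampling under a rigid
#' transform) a shared grid, compute the ice-ball signed distance field, the
#' per-surface-point margin map, the margin summary with octant and coverage
#' decomposition, and tumor/ice morphometry.
#'
#' @param tumor,ice [binary_mask()] objects.
#' @param transform optional [rigid_transform()] mapping the ice-ball world
#'   frame into the tumor frame; when given (or when grids differ), the ice
#'   mask is resampled onto the tumor grid first.
#' @param threshold_mm intended margin threshold, mm.
#' @return A list of class \code{margin_report} with \code{summary},
#'   \code{map}, \code{tumor_morphometry}, \code{ice_morphometry}.
#' @export
margin_analysis <- function(tumor, ice, transform = NULL, threshold_mm = 5) {
  if (!is.null(transform)) {
    ice <- resample_mask(ice, tumor$geometry, transform)
  } else {
    grids_match <- tryCatch({assert_same_grid(tumor, ice); TRUE},
                            error = function(e) FALSE)
    if (!grids_match) ice <- resample_mask(ice, tumor$geometry)
  }
  ice_sdf <- signed_distance_field(ice)
  map <- compute_margin_map(tumor, ice, ice_sdf = ice_sdf)
  summ <- summarize_margin(map, tumor, ice, threshold_mm = threshold_mm,
                           ice_sdf = ice_sdf)
  structure(list(summary = summ, map = map,
                 tumor_morphometry = morphometry(tumor),
                 ice_morphometry = morphometry(ice)),
            class = "margin_report")
}

#' @export
print.margin_report <- function(x, ...) {
  print(x$summary)
  cat("  tumor: ", signif(x$tumor_morphometry$volume_ml, 3), " ml, max 3D diameter ",
      signif(x$tumor_morphometry$max_diameter_mm, 3), " mm\n", sep = "")
  cat("  ice ball: ", signif(x$ice_morphometry$volume_ml, 3), " ml\n",
      sep = "")
  invisible(x)
}

report_to_list <- function(report) {
  s <- report$summary
  list(mtm_mm = s$mtm_mm,
       mtm_raw_mm = s$mtm_raw_mm,
       argmin_xyz_mm = s$argmin_xyz_mm,
       argmin_octant = s$argmin_octant,
       octant_min_mm = as.list(s$octant_min_mm),
       coverage_fractions = as.list(s$coverage_fractions),
       threshold_mm = s$threshold_mm,
       margin_achieved = s$margin_achieved,
       tumor_volume_ml = report$tumor_morphometry$volume_ml,
       iceball_volume_ml = report$ice_morphometry$volume_ml,
       max_diameter_mm = report$tumor_morphometry$max_diameter_mm,
       voxel_diagonal_mm = s$voxel_diagonal_mm,
       version = as.character(utils::packageVersion("cryomargin")))
}

#' Run the margin pipeline on files and write a JSON report
#'
#' File-level entry point: reads NIfTI masks, obtains the co-registration
#' (from a transform JSON, from landmark CSVs, or assumes pre-registered
#' grids), runs [margin_analysis()], and writes the report JSON (and
#' optionally the margin map as NIfTI).
#'
#' @param tumor_path,ice_path NIfTI mask paths.
#' @param out_path output JSON path.
#' @param transform_path optional rigid-transform JSON (ice -> tumor frame).
#' @param landmarks_source_path,landmarks_target_path optional landmark CSVs
#'   (ice-frame source, tumor-frame target) to fit the transform; mutually
#'   exclusive with \code{transform_path}.
#' @param threshold_mm intended margin, mm.
#' @param margin_map_path optional NIfTI output for the surface margin map.
#' @return Invisibly, the report list that was serialized.
#' @export
cmd_margin <- function(tumor_path, ice_path, out_path,
                       transform_path = NULL,
                       landmarks_source_path = NULL,
                       landmarks_target_path = NULL,
                       threshold_mm = 5,
                       margin_map_path = NULL) {
  if (!is.null(transform_path) && !is.null(landmarks_source_path))
    stop("give either a transform file or landmark files, not both",
         call. = FALSE)
  tumor <- read_mask(tumor_path)
  ice <- read_mask(ice_path)
  transform <- NULL
  if (!is.null(transform_path)) {
    transform <- read_transform(transform_path)
  } else if (!is.null(landmarks_source_path)) {
    if (is.null(landmarks_target_path))
      stop("landmark registration needs both source and target CSVs",
           call. = FALSE)
    transform <- fit_rigid(read_landmarks(landmarks_source_path),
                           read_landmarks(landmarks_target_path))
  }
  report <- margin_analysis(tumor, ice, transform = transform,
                            threshold_mm = threshold_mm)
  if (!is.null(margin_map_path)) write_margin_map(report$map,
                                                  margin_map_path)
  out <- report_to_list(report)
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(out)
}

#' Cohort outcome statistics
#'
#' The full statistical battery on a per-case cohort: group descriptives and
#' Mann-Whitney comparisons of continuous baselines between local-control
#' and progression cases, exact tests on the categorical covariates (Fisher
#' for sex and ASA, Freeman-Halton for the three RENAL categories), the
#' Spearman size-margin correlation, univariable Cox models for margin
#' (per mm) and tumor diameter (per cm), and Kaplan-Meier progression-free
#' estimates.
#'
#' @param records cohort data frame (validated; see [read_cohort_csv()]).
#' @param km_horizons_months Kaplan-Meier evaluation times.
#' @return A list of class \code{cohort_stats}.
#' @export
cohort_stats <- function(records, km_horizons_months = c(12, 24)) {
  records <- validate_cohort(records)
  g <- records$ltp
  grp <- function(x) list(control = x[!g], ltp = x[g])

  describe <- function(x) {
    c(list(mean = mean(x), sd = stats::sd(x)), as.list(median_iqr(x)))
  }
  continuous <- list()
  for (v in c("tumor_diameter_mm", "tumor_volume_ml", "iceball_volume_ml",
              "mtm_raw_mm", "n_probes")) {
    if (is.null(records[[v]])) next
    s <- grp(as.numeric(records[[v]]))
    continuous[[v]] <- list(
      control = describe(s$control), ltp = describe(s$ltp),
      test = if (length(s$control) && length(s$ltp))
        mann_whitney_u(s$control, s$ltp) else NULL)
  }

  categorical <- list()
  tab2 <- function(x) table(factor(x), factor(g, levels = c(FALSE, TRUE)))
  if (!is.null(records$sex)) {
    t <- tab2(records$sex)
    if (identical(dim(t), c(2L, 2L)))
      categorical$sex <- list(counts = unclass(t),
                              test = fisher_exact_2x2(t))
  }
  if (!is.null(records$asa)) {
    t <- tab2(records$asa)
    if (identical(dim(t), c(2L, 2L)))
      categorical$asa <- list(counts = unclass(t),
                              test = fisher_exact_2x2(t))
  }
  if (!is.null(records$renal_category)) {
    t <- table(factor(records$renal_category,
                      levels = c("low", "moderate", "high")),
               factor(g, levels = c(FALSE, TRUE)))
    categorical$renal_category <- list(counts = unclass(t),
                                       test = freeman_halton(t))
  }

  correlation <- spearman_rho(records$tumor_diameter_mm, records$mtm_raw_mm)

  cox <- list()
  for (v in c("mtm_raw_mm", "tumor_diameter_mm")) {
    cox[[v]] <- tryCatch(cox_univariable(records, v),
                         error = function(e) e$message)
  }

  km <- km_event_free(records, km_horizons_months)

  structure(list(n = nrow(records), n_ltp = sum(g),
                 continuous = continuous, categorical = categorical,
                 size_margin_correlation = correlation,
                 cox = cox, km_event_free = km),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("Cohort: ", x$n, " cases, ", x$n_ltp, " with local tumor progression\n",
      sep = "")
  for (v in names(x$continuous)) {
    e <- x$continuous[[v]]
    cat(sprintf("  %-18s control %.1f (%.1f-%.1f) vs LTP %.1f (%.1f-%.1f)",
                v, e$control$median, e$control$q1, e$control$q3,
                e$ltp$median, e$ltp$q1, e$ltp$q3))
    if (!is.null(e$test)) cat(sprintf("  p = %.3g", e$test$p_value))
    cat("\n")
  }
  for (v in names(x$categorical))
    cat(sprintf("  %-18s %s p = %.3g\n", v,
                x$categorical[[v]]$test$method,
                x$categorical[[v]]$test$p_value))
  cat(sprintf("  size vs margin     Spearman rho = %.2f, p = %.3g\n",
              x$size_margin_correlation$statistic,
              x$size_margin_correlation$p_value))
  for (v in names(x$cox)) {
    cr <- x$cox[[v]]
    if (inherits(cr, "cox_result"))
      cat(sprintf("  Cox %-15s HR %.2f (%.2f-%.2f, %s), p = %.3g\n", v,
                  cr$hazard_ratio, cr$ci95[1], cr$ci95[2], cr$unit,
                  cr$p_value))
    else cat("  Cox ", v, ": ", cr, "\n", sep = "")
  }
  cat("  LTP-free survival: ",
      paste(sprintf("%s %.1f%%", names(x$km_event_free),
                    100 * x$km_event_free), collapse = ", "), "\n", sep = "")
  invisible(x)
}

stats_to_list <- function(x) {
  strip <- function(o) {
    if (inherits(o, "margin_test"))
      return(list(statistic = o$statistic, p_value = o$p_value,
                  method = o$method, n = as.numeric(o$n)))
    if (inherits(o, "cox_result"))
      return(list(hazard_ratio = o$hazard_ratio, ci95 = o$ci95,
                  p_value = o$p_value, n_events = o$n_events,
                  unit = o$unit))
    if (is.list(o)) return(lapply(o, strip))
    if (is.matrix(o)) return(apply(o, 1, as.numeric, simplify = FALSE))
    o
  }
  strip(unclass(x))
}

#' Run the cohort-statistics pipeline on a CSV and write reports
#'
#' @param cases_csv cohort CSV path.
#' @param out_path output JSON path.
#' @param text_path optional path for the human-readable text report.
#' @return Invisibly, the [cohort_stats()] object.
#' @export
cmd_cohort_stats <- function(cases_csv, out_path, text_path = NULL) {
  records <- read_cohort_csv(cases_csv)
  st <- cohort_stats(records)
  out <- stats_to_list(st)
  out$version <- as.character(utils::packageVersion("cryomargin"))
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); print(st); sink()
    close(con)
  }
  invisible(st)
}

#' Convenience sphere-pair phantom
#'
#' Builds a [phantom_spec()] for a tumor sphere and an ice sphere with a
#' prescribed analytic minimal margin, sizing the grid automatically.
#'
#' @param r_tumor,r_ice sphere radii, mm.
#' @param offset_mm distance between centers, mm (so the analytic margin is
#'   \code{r_ice - offset_mm - r_tumor}).
#' @param spacing voxel spacing, mm.
#' @param direction unit-ish vector along which the ice center is offset.
#' @return List as returned by [make_phantom()].
#' @export
sphere_pair_phantom <- function(r_tumor, r_ice, offset_mm = 0,
                                spacing = c(1, 1, 1),
                                direction = c(1, 0, 0)) {
  direction <- direction / sqrt(sum(direction^2))
  ext <- offset_mm / 2 + max(r_tumor, r_ice)
  shape <- ceiling((2 * ext + 8 * spacing) / spacing)
  center <- (shape - 1) / 2 * spacing - offset_mm / 2 * direction
  make_phantom(phantom_spec(
    shape, spacing,
    tumor = list(center = center, semiaxes = r_tumor),
    ice = list(center = center + offset_mm * direction, semiaxes = r_ice)))
}
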