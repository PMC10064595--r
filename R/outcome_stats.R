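test_result <- function(statistic, p_value, method, n) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n), class = "margin_test")
}

#' @export
print.margin_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4), ", p = ",
      signif(x$p_value, 3), " (n = ", paste(x$n, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples, the test used
#' for non-normally distributed continuous baseline variables (e.g. the
#' minimal treatment margin between local-control and progression groups).
#' The exact distribution is used when \code{n_x * n_y <= 400} and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @return A test result with the U statistic (for \code{x}).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  test_result(unname(wt$statistic), wt$p.value,
              if (use_exact) "Mann-Whitney U (exact)"
              else "Mann-Whitney U (normal approximation)",
              c(length(x), length(y)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability method: the sum of hypergeometric
#' probabilities, over tables with the observed margins, of every table no
#' more probable than the observed one (the convention SPSS reports).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A test result; the statistic is the conditional odds ratio
#'   estimate.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)))
    stop("`table` must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(table) < 1)
    stop("table is empty", call. = FALSE)
  ft <- stats::fisher.test(table)
  test_result(unname(ft$estimate), ft$p.value, "Fisher's exact test",
              rowSums(table))
}

# enumerate all r x c tables with the given margins, calling fun(tab) on each
enumerate_rc_tables <- function(rows, cols, fun) {
  r <- length(rows); c <- length(cols)
  tab <- matrix(0L, r, c)
  recurse <- function(i, rem_cols) {
    if (i == r) {
      tab[r, ] <<- rem_cols
      fun(tab)
      return(invisible())
    }
    # last cell of the row is determined; iterate the first c-1 freely,
    # tracking the remaining column capacities
    fill_free <- function(j, rem_row, rc) {
      if (j == c) {
        if (rem_row <= rc[c]) {
          tab[i, c] <<- rem_row
          rc2 <- rc; rc2[c] <- rc2[c] - rem_row
          recurse(i + 1L, rc2)
        }
        return(invisible())
      }
      hi <- min(rem_row, rc[j])
      for (v in 0:hi) {
        tab[i, j] <<- v
        rc2 <- rc; rc2[j] <- rc2[j] - v
        fill_free(j + 1L, rem_row - v, rc2)
      }
    }
    fill_free(1L, rows[i], rem_cols)
  }
  recurse(1L, cols)
  invisible()
}

# log multivariate-hypergeometric probability of a table under fixed margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Fisher-Freeman-Halton exact test for an r x c table
#'
#' Exact generalization of Fisher's test to tables with more than two rows
#' or columns (e.g. three RENAL complexity categories against outcome).
#' Enumerates every table with the observed margins under the multivariate
#' hypergeometric null and sums the probabilities of tables no more probable
#' than the observed one (with a 1e-7 relative slack for floating-point
#' ties). Enumeration is limited to \code{r*c <= 12} cells and a grand total
#' of 200; beyond that, set \code{monte_carlo = TRUE} for a seeded
#' Patefield-sampling approximation.
#'
#' @param table r x c matrix of nonnegative integer counts.
#' @param monte_carlo use Monte-Carlo approximation instead of enumeration.
#' @param n_draws,seed Monte-Carlo sample size and seed.
#' @return A test result; the statistic is the observed table probability.
#' @export
freeman_halton <- function(table, monte_carlo = FALSE, n_draws = 100000,
                           seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  storage.mode(table) <- "integer"
  rows <- rowSums(table); cols <- colSums(table)
  lp_obs <- log_table_prob(table)
  n <- c(rows, use.names = FALSE)

  if (!monte_carlo) {
    if (length(table) > 12L || sum(table) > 200L)
      stop("table too large for exact enumeration (limit: 12 cells, ",
           "grand total 200); call with monte_carlo = TRUE", call. = FALSE)
    # degenerate margins (a zero row/column, or a single row/column) leave a
    # single attainable table, so p = 1 by enumeration below
    acc_p <- 0
    enumerate_rc_tables(rows, cols, function(tab) {
      lp <- log_table_prob(tab)
      if (lp <= lp_obs + log1p(1e-7)) acc_p <<- acc_p + exp(lp)
    })
    p <- min(1, acc_p)
    method <- "Fisher-Freeman-Halton exact test"
  } else {
    set.seed(seed)
    draws <- stats::r2dtable(n_draws, rows, cols)
    lps <- vapply(draws, log_table_prob, numeric(1))
    p <- mean(lps <= lp_obs + log1p(1e-7))
    method <- sprintf("Fisher-Freeman-Halton (Monte-Carlo, %d draws)",
                      n_draws)
  }
  test_result(exp(lp_obs), p, method, n)
}

# total probability mass of the enumerated support (diagnostic; must be 1)
fh_support_mass <- function(table) {
  table <- as.matrix(table); storage.mode(table) <- "integer"
  total <- 0
  enumerate_rc_tables(rowSums(table), colSums(table),
                      function(tab) total <<- total + exp(log_table_prob(tab)))
  total
}

#' Spearman rank correlation
#'
#' Midrank-based rho with a two-sided p-value from the t approximation on
#' n - 2 degrees of freedom; used for the tumor-size vs. margin association.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return A test result with rho as the statistic.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    alternative = "two.sided"))
  test_result(unname(ct$estimate), ct$p.value,
              "Spearman rank correlation (t approximation)", length(x))
}

#' Univariable Cox proportional-hazards regression
#'
#' Fits the partial likelihood for a single covariate against time to local
#' tumor progression with right censoring, Breslow tie handling by default.
#' Covariates are entered on clinically conventional scales: the margin per
#' millimeter, the tumor diameter per centimeter (set via \code{scale}).
#'
#' @param records a cohort data frame (see [simulate_cohort()] /
#'   [read_cohort_csv()]) with columns \code{time_months} and \code{event}.
#' @param covariate name of a numeric column.
#' @param scale divisor applied to the covariate before fitting (e.g. 10 to
#'   express a per-cm hazard ratio for a mm-valued diameter). Defaults: 10
#'   for \code{tumor_diameter_mm}, otherwise 1.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @return A list of class \code{cox_result}: \code{hazard_ratio},
#'   \code{ci95}, \code{p_value}, \code{coef}, \code{se}, \code{n_events},
#'   \code{unit}.
#' @export
cox_univariable <- function(records, covariate,
                            scale = if (covariate == "tumor_diameter_mm") 10
                                    else 1,
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  for (col in c("time_months", "event", covariate))
    if (is.null(records[[col]]))
      stop("cohort is missing column `", col, "`", call. = FALSE)
  z <- as.numeric(records[[covariate]]) / scale
  ev <- as.logical(records$event)
  if (sum(ev) == 0L)
    stop("inestimable: no events in the cohort", call. = FALSE)
  if (stats::sd(z) == 0)
    stop("inestimable: covariate has zero variance", call. = FALSE)
  ws <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(records$time_months, ev) ~ z, ties = ties,
      control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      ws <<- c(ws, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("infinite|converge", ws)))
    warning("monotone partial likelihood (perfect separation): ",
            "coefficient capped at the last Newton-Raphson iterate",
            call. = FALSE)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  zstat <- beta / se
  structure(list(
    hazard_ratio = exp(beta),
    ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(zstat)),
    coef = beta, se = se,
    n_events = sum(ev), n = length(ev),
    covariate = covariate,
    unit = if (scale == 10) "per cm"
           else if (grepl("_mm$", covariate)) "per mm"
           else "per unit",
    ties = ties), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox (", x$ties, " ties) ", x$covariate, " [", x$unit, "]: HR = ",
      signif(x$hazard_ratio, 3), " (95% CI ", signif(x$ci95[1], 3), "-",
      signif(x$ci95[2], 3), "), p = ", signif(x$p_value, 3), ", ",
      x$n_events, "/", x$n, " events\n", sep = "")
  invisible(x)
}

#' Kaplan-Meier event-free probability at given horizons
#'
#' Product-limit estimate of the probability of remaining free of local
#' tumor progression, evaluated right-continuously at each horizon.
#'
#' @param records cohort data frame with \code{time_months} and
#'   \code{event}.
#' @param horizons_months nonnegative times (months) at which to evaluate.
#' @return Named numeric vector of survival probabilities.
#' @export
km_event_free <- function(records, horizons_months = c(12, 24)) {
  if (any(horizons_months < 0))
    stop("horizons must be nonnegative", call. = FALSE)
  if (nrow(records) == 0L)
    stop("empty cohort", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(records$time_months, as.logical(records$event)) ~ 1)
  s <- summary(fit, times = horizons_months, extend = TRUE)$surv
  stats::setNames(s, paste0(horizons_months, "mo"))
}

# median and Tukey-hinge IQR, the descriptive convention used in reports
median_iqr <- function(x) {
  f <- stats::fivenum(x)
  c(median = f[3], q1 = f[2], q3 = f[4])
}
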