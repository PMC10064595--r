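test_that("Mann-Whitney U covers exact, approximate, and tied branches", {
  # identical samples, tied -> approximation branch, no separation
  x <- c(1, 2, 3, 4, 5)
  r <- mann_whitney_u(x, x)
  expect_match(r$method, "approximation")
  expect_equal(r$p_value, 1)

  # small untied samples -> exact enumeration: U = 0, p = 2/20
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_match(r2$method, "exact")
  expect_equal(r2$p_value, 0.1)

  # perfectly separated n = 13 vs 13 (approximation branch: 169 > 400 is
  # false -> still exact); p below 0.001 either way
  r3 <- mann_whitney_u(1:13, 14:26)
  expect_lt(r3$p_value, 0.001)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate Mann-Whitney agree within 0.02", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(9); y <- rnorm(9, 0.5)
    exact <- mann_whitney_u(x, y)$p_value
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("Fisher's exact test reproduces the published 2x2 p-values", {
  # sex (control/LTP) and ASA class tables from the study cohort
  expect_lt(abs(fisher_exact_2x2(rbind(c(17, 3), c(9, 3)))$p_value - 0.647),
            5e-4)
  expect_lt(abs(fisher_exact_2x2(rbind(c(17, 2), c(9, 4)))$p_value - 0.194),
            5e-4)
  # degenerate margin: a zero row leaves only one attainable table
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(5, 3)))$p_value, 1)
  expect_error(fisher_exact_2x2(rbind(c(-1, 0), c(5, 3))), "nonnegative")
})

test_that("Freeman-Halton reproduces the published 3x2 p-value", {
  renal <- rbind(c(18, 2), c(8, 3), c(0, 1))
  r <- freeman_halton(renal)
  expect_lt(abs(r$p_value - 0.070), 5e-4)
  expect_match(r$method, "exact")
})

test_that("Freeman-Halton enumeration probabilities sum to one", {
  tabs <- list(rbind(c(18, 2), c(8, 3), c(0, 1)),
               rbind(c(3, 1, 2), c(0, 4, 1)),
               rbind(c(5, 0), c(0, 5)))
  for (tab in tabs)
    expect_equal(cryomargin:::fh_support_mass(tab), 1, tolerance = 1e-9)
})

test_that("Freeman-Halton reduces to Fisher's test on 2x2 tables", {
  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(freeman_halton(tab)$p_value,
                 fisher_exact_2x2(tab)$p_value, tolerance = 1e-9)
  }
  # and an exhaustive sweep over small tables
  for (a in 0:3) for (b in 0:3) for (c in 0:3) for (d in 0:3) {
    tab <- rbind(c(a, b), c(c, d))
    if (sum(tab) == 0) next
    expect_equal(freeman_halton(tab)$p_value,
                 fisher_exact_2x2(tab)$p_value, tolerance = 1e-9)
  }
})

test_that("Freeman-Halton degenerate and oversized tables", {
  expect_equal(freeman_halton(matrix(c(3, 2, 1), 3, 1))$p_value, 1)
  big <- matrix(50L, 3, 3)
  expect_error(freeman_halton(big), "monte_carlo")
  # Monte-Carlo fallback approximates the exact answer
  renal <- rbind(c(18, 2), c(8, 3), c(0, 1))
  mc <- freeman_halton(renal, monte_carlo = TRUE, n_draws = 20000,
                       seed = 7)
  expect_lt(abs(mc$p_value - 0.0702), 0.01)
})

test_that("Spearman correlation handles monotone and constant input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_rho(x, x)$statistic, 1)
  expect_lt(spearman_rho(x, x)$p_value, 1e-4)
  expect_equal(spearman_rho(x, -x)$statistic, -1)
  expect_error(spearman_rho(x, rep(1, 7)), "constant")
  expect_error(spearman_rho(1:4, 1:5), "paired")
})

test_that("Cox partial likelihood matches a hand-derived closed form", {
  # three subjects, events at t = 1 (z = 0) and t = 2 (z = 1), one censored:
  # d/db log PL = 1 - u/(u+2) - u/(u+1) = 0 with u = e^b  =>  u^2 = 2,
  # so beta-hat = log(2)/2
  rec <- data.frame(time_months = c(1, 2, 3),
                    event = c(TRUE, TRUE, FALSE),
                    z = c(0, 1, 0))
  fit <- cox_univariable(rec, "z")
  expect_equal(fit$coef, log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$hazard_ratio, sqrt(2), tolerance = 1e-6)
  expect_true(fit$ci95[1] <= fit$hazard_ratio &&
                fit$hazard_ratio <= fit$ci95[2])
})

test_that("Cox recovers the null for an independent covariate", {
  set.seed(42)
  n <- 500
  rec <- data.frame(time_months = rexp(n, 0.05),
                    event = rep(TRUE, n),
                    z = rnorm(n))
  fit <- cox_univariable(rec, "z")
  expect_gt(fit$hazard_ratio, 0.85)
  expect_lt(fit$hazard_ratio, 1.18)
})

test_that("perfect separation triggers a divergence warning", {
  # the subject with the larger covariate always progresses first
  rec <- data.frame(time_months = c(1, 2, 3, 4),
                    event = c(TRUE, TRUE, FALSE, FALSE),
                    z = c(2, 1.5, 0.5, 0))
  expect_warning(fit <- cox_univariable(rec, "z"), "separation")
  expect_true(is.finite(fit$coef))
})

test_that("Cox errors are informative for inestimable cohorts", {
  rec <- data.frame(time_months = c(5, 10), event = c(FALSE, FALSE),
                    z = c(1, 2))
  expect_error(cox_univariable(rec, "z"), "no events")
  rec2 <- data.frame(time_months = c(5, 10), event = c(TRUE, TRUE),
                     z = c(1, 1))
  expect_error(cox_univariable(rec2, "z"), "variance")
})

test_that("tumor diameter enters the Cox model per centimeter", {
  sim <- simulate_cohort(cohort_spec(n_cases = 300), seed = 9)
  per_cm <- cox_univariable(sim$records, "tumor_diameter_mm")
  expect_identical(per_cm$unit, "per cm")
  manual <- sim$records
  manual$diam_cm <- manual$tumor_diameter_mm / 10
  ref <- cox_univariable(manual, "diam_cm")
  expect_equal(per_cm$hazard_ratio, ref$hazard_ratio, tolerance = 1e-9)
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  rec <- data.frame(time_months = c(6, 12, 18, 24),
                    event = c(TRUE, FALSE, TRUE, FALSE))
  s <- km_event_free(rec, c(12, 24))
  expect_equal(unname(s[1]), 0.75)
  expect_equal(unname(s[2]), 0.375)

  none <- data.frame(time_months = c(5, 10, 15), event = rep(FALSE, 3))
  expect_equal(unname(km_event_free(none, c(6, 12, 60))), c(1, 1, 1))
  expect_error(km_event_free(rec, -2), "nonnegative")
})

test_that("Kaplan-Meier without censoring equals the empirical survival", {
  set.seed(3)
  t <- rexp(40, 0.1)
  rec <- data.frame(time_months = t, event = rep(TRUE, 40))
  hz <- c(2, 5, 10, 20)
  expect_equal(unname(km_event_free(rec, hz)),
               vapply(hz, function(h) mean(t > h), numeric(1)))
})
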