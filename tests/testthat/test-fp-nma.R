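test_that("interval counts from IPD match hand counts and conserve events", {
  ipd <- data.frame(trial = "t", arm = "a", time = c(1, 2, 3), event = 1)
  ic <- interval_counts_from_ipd(ipd, c(0, 2, 4))
  expect_equal(ic$n_at_risk, c(3, 2))
  expect_equal(ic$events, c(1, 2))
  ipd2 <- sim_ph_trial(seed = 61, n = 400, dropout = 0.02)
  ic2 <- interval_counts_from_ipd(ipd2, c(0:24, 36))
  expect_equal(sum(ic2$events), sum(ipd2$event))
})

test_that("fine interval hazards track a constant hazard", {
  sp <- trial_spec("t", n_per_arm = 10000,
                   reference_hazard = list(breaks = 0, rates = 0.1),
                   accrual_months = 0, cutoff_months = 20, seed = 62)
  ipd <- simulate_trial(sp)
  ic <- interval_counts_from_ipd(ipd[ipd$arm == "reference", ],
                                 seq(0, 10, 0.5))
  h_hat <- ic$events / (ic$n_at_risk * (ic$b - ic$a))
  expect_true(all(abs(h_hat - 0.1) / 0.1 < 0.2))
})

test_that("expected counts from survival match closed forms", {
  ic <- interval_counts_from_survival(function(t) exp(-0.1 * t), 100, 0:1)
  expect_equal(ic$events, 100 * (1 - exp(-0.1)), tolerance = 1e-10)
  ic2 <- interval_counts_from_survival(function(t) exp(-0.07 * t), 500,
                                       0:24, cutoff = 30, accrual = 8)
  expect_true(all(diff(ic2$n_at_risk) <= 1e-9))
  ## constant hazard in, near-constant interval hazard out (Taylor bound)
  h_out <- ic2$events / (ic2$n_at_risk * (ic2$b - ic2$a))
  expect_true(all(abs(h_out - 0.07) / 0.07 <= 0.07 / 2 + 1e-6))
  expect_error(interval_counts_from_survival(function(t) 1 + t, 10, 0:2),
               "non-increasing")
})

test_that("a null contrast is estimated near zero with honest intervals", {
  sp <- trial_spec("t", n_per_arm = 1500,
                   reference_hazard = list(breaks = 0, rates = 0.1),
                   accrual_months = 0, cutoff_months = 24, seed = 63)
  ipd <- simulate_trial(sp)
  ipd$arm <- ifelse(ipd$arm == "reference", "chemotherapy", "drugA")
  f <- fit_fp1(interval_counts_from_ipd(ipd, c(0:18, 24)), p = -1)
  se_d0 <- (f$contrasts$d0_high - f$contrasts$d0) / 1.96
  se_d1 <- (f$contrasts$d1_high - f$contrasts$d1) / 1.96
  expect_lt(abs(f$contrasts$d0), 3 * se_d0)
  expect_lt(abs(f$contrasts$d1), 3 * se_d1)
})

test_that("printed-contrast expected counts round-trip through the fit", {
  ## toripalimab PFS row: d0 = -0.91, d1 = 2.76 at p = -2
  cnt <- fp_surface_counts(d0 = -0.91, d1 = 2.76, p = -2,
                           arm = "toripalimab")
  f <- fit_fp1(cnt, p = -2)
  expect_lt(abs(f$contrasts$d0 + 0.91), 0.05)
  expect_lt(abs(f$contrasts$d1 - 2.76), 0.05)
  expect_equal(f$i_squared, 0)
})

test_that("degenerate arms and broken networks are rejected", {
  cnt <- fp_surface_counts(d0 = -0.5, d1 = 0, p = -1)
  bad <- cnt
  bad$events[bad$arm == "treatment"] <- 0
  expect_error(fit_fp1(bad, p = -1), "no events")
  orphan <- cnt[cnt$arm != "chemotherapy", ]
  expect_error(fit_fp1(orphan, p = -1), "reference")
})

test_that("scan_powers ranks the generating power first", {
  cnt <- fp_surface_counts(d0 = -0.6, d1 = 1.5, p = -2)
  sc <- scan_powers(cnt, p_grid = c(-2, -1), orders = 1)
  expect_equal(sc$ranking$p[1], -2)
  expect_equal(nrow(sc$ranking), 2)
  sc1 <- scan_powers(cnt, p_grid = 0.5, orders = 1)
  expect_equal(sc1$selected$p, 0.5)
  ## default grid: one row per cell, converged cells ranked by AIC
  sc2 <- scan_powers(cnt, p_grid = c(-2, -1, 0, 1), orders = c(1, 2))
  expect_equal(nrow(sc2$ranking), 8)
  ok <- sc2$ranking$converged & !is.na(sc2$ranking$aic)
  expect_true(all(diff(sc2$ranking$aic[ok]) >= -1e-9))
})

test_that("hr_curve evaluates the FP contrast with its conventions", {
  expect_equal(hr_curve(list(d0 = 0, d1 = 0, p = -1), c(0.5, 2, 10)),
               rep(1, 3))
  expect_equal(hr_curve(list(d0 = -0.45, d1 = -0.56, p = -1), 1e9),
               exp(-0.45), tolerance = 1e-6)
  ## p = -2 with d1 > 0: monotone decreasing towards exp(d0)
  hh <- hr_curve(list(d0 = -0.3, d1 = 1.2, p = -2), seq(1, 50, 1))
  expect_true(all(diff(hh) < 0))
  expect_equal(hh[50], exp(-0.3), tolerance = 0.01)
  ## p = 0 uses log t
  expect_equal(hr_curve(list(d0 = 0.1, d1 = 0.2, p = 0), exp(1)),
               exp(0.1 + 0.2))
  expect_error(hr_curve(list(d0 = 0, d1 = 1, p = -1), c(0, 1)), "> 0")
})

test_that("apply_contrast reproduces identities and the quadrature oracle", {
  set.seed(64)
  x <- data.frame(time = rexp(800, 0.1), event = 1)
  fit <- fit_parametric(x, "exponential")
  grid <- seq(0, 24, 0.5)
  ## null contrast: the reference curve back, to 1e-8
  s0 <- apply_contrast(fit, list(d0 = 0, d1 = 0, p = -1), grid)
  expect_lt(max(abs(s0$survival - predict(fit, grid)$survival)), 1e-8)
  ## proportional shift of a constant hazard: closed form
  rate <- unname(fit$coefficients[["rate"]])
  s1 <- apply_contrast(fit, list(d0 = log(0.5), d1 = 0, p = -1), grid)
  expect_equal(s1$survival[grid == 10], exp(-rate * 0.5 * 10),
               tolerance = 1e-8)
  ## time-varying contrast: agree with a 10x-refined trapezoid
  ct <- list(d0 = -0.4, d1 = 0.6, p = -1)
  s2 <- apply_contrast(fit, ct, grid)
  fine <- seq(0, 24, length.out = 10 * length(grid) * 10)
  integ <- rate * exp(ct$d0 + ct$d1 * pmax(fine, 1)^ct$p)
  ch <- cumsum(c(0, (integ[-1] + integ[-length(integ)]) / 2 * diff(fine)))
  s_ref <- exp(-stats::approx(fine, ch, xout = grid)$y)
  expect_lt(max(abs(s2$survival - s_ref)), 1e-5)
  ## a proper survival function in every case
  expect_equal(s2$survival[1], 1)
  expect_true(all(diff(s2$survival) <= 0))
  expect_true(all(s2$survival >= 0 & s2$survival <= 1))
  ## divergent integrands are flagged
  expect_error(apply_contrast(fit, list(d0 = 0, d1 = 900, p = 1), grid),
               "divergent")
})

test_that("the fitted model beats the no-treatment-effect null", {
  cnt <- sim_fp_network_counts(seed = 3, n = 800, n_trials = 2)
  full <- fit_fp1(cnt, p = -2)
  null_data <- cnt
  null_data$arm <- "chemotherapy"
  null_data <- stats::aggregate(cbind(n_at_risk, events, censored) ~
                                  trial + arm + a + b,
                                data = null_data, FUN = sum)
  null <- fit_fp1(null_data, p = -2)
  expect_gte(full$loglik, null$loglik)
})

test_that("with d1 fixed at zero the fit agrees with Cox", {
  ipd <- sim_ph_trial(seed = 65, n = 5000, log_hr = log(0.7))
  ipd$arm <- ifelse(ipd$arm == "reference", "chemotherapy", "drugA")
  cox <- cox_hr(ipd, reference = "chemotherapy")
  f <- fit_fp1(interval_counts_from_ipd(ipd, c(0:24, 36)), p = -1,
               fix_d1 = TRUE)
  expect_lt(abs(exp(f$contrasts$d0) - cox$hr_point) / cox$hr_point, 0.10)
  expect_equal(f$contrasts$d1, 0)
})

test_that("heterogeneity is zero when homogeneous and grows when induced", {
  cnt <- rbind(fp_surface_counts(d0 = -0.5, d1 = 0.3, p = -1),
               within(fp_surface_counts(d0 = -0.5, d1 = 0.3, p = -1),
                      trial <- "t2"))
  f <- fit_fp1(cnt, p = -1)
  expect_equal(heterogeneity(f), 0)
  ## inflate one trial's event counts
  infl <- cnt
  sel <- infl$trial == "t2"
  infl$events[sel] <- pmin(infl$events[sel] * 2, infl$n_at_risk[sel])
  f2 <- fit_fp1(infl, p = -1)
  expect_gte(heterogeneity(f2), heterogeneity(f))
  expect_gte(f2$i_squared, 0)
  expect_lte(f2$i_squared, 100)
})

test_that("contrast tables survive the CSV round trip", {
  tab <- escc_fp_contrasts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_contrasts_csv(tab, path)
  expect_equal(read_contrasts_csv(path), tab)
})
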