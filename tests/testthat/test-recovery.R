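test_that("deplete scales the stem pool and leaves concentration untouched", {
  expect_equal(deplete(c(s = 20, c = 1), 0.9), c(s = 2, c = 1))
  expect_equal(deplete(c(s = 20, c = 1), 0), c(s = 20, c = 1))
  expect_error(deplete(c(s = 20, c = 1), 1.2), "\\[0, 1\\]")
  # total depletion is absorbing in the mean-field model
  p <- p_default()
  tr <- simulate_density(p, init = deplete(c(s = 20, c = 1), 1),
                         times = seq(0, 100, 1))
  expect_true(all(tr$s == 0))
  expect_true(attr(tr, "extinct"))
})

test_that("oscillation detection separates monotone and oscillatory regimes", {
  # constant trajectory: nothing to detect
  flat <- tibble::tibble(time = seq(0, 100, 1), s = rep(20, 101))
  rep0 <- detect_oscillation(flat, 20)
  expect_false(rep0$overshoot)
  expect_identical(rep0$n_extrema, 0L)

  # real eigenvalues: monotone recovery, no overshoot (eigen-oracle regime)
  p_mono <- p_default()
  expect_false(steady_state(p_mono)$oscillatory)
  tr_mono <- simulate_density(p_mono, init = deplete(c(s = 20, c = 1), 0.9),
                              times = seq(0, 400, 0.25))
  expect_false(detect_oscillation(tr_mono, 20)$overshoot)

  # complex eigenvalues: overshoot, period within 5% of 2*pi/Im(eigenvalue)
  p_osc <- p_oscillatory()
  fp <- steady_state(p_osc)
  expect_true(fp$oscillatory)
  tr_osc <- simulate_density(p_osc, init = deplete(fp$homeostatic, 0.9),
                             times = seq(0, 300, 0.25))
  rep_osc <- detect_oscillation(tr_osc, fp$homeostatic[["s"]])
  expect_true(rep_osc$overshoot)
  expect_true(rep_osc$period_defined)
  expect_equal(rep_osc$period_days, 2 * pi / fp$damped_frequency, tolerance = 0.05)
})

test_that("noiseless synthetic series is fit back to the generating parameters", {
  p <- p_oscillatory()
  truth <- c(lam = p$lam, k = p$k, kappa = p$kprime * 20 / p$c0)
  ser <- gen_recovery_series(p, depletion_fraction = 0.9, noise_cv = 0, seed = 1)
  fit <- fit_recovery(ser, n_starts = 16, seed = 1)
  expect_equal(fit$par[["lam"]], truth[["lam"]], tolerance = 0.01)
  expect_equal(fit$par[["k"]], truth[["k"]], tolerance = 0.01)
  expect_equal(fit$par[["kappa"]], truth[["kappa"]], tolerance = 0.01)
  expect_equal(fit$par[["x0"]], 0.1, tolerance = 0.01)
  expect_equal(fit$par[["y0"]], 1, tolerance = 0.01)
  expect_lt(fit$rss, 1e-8)
  g <- glance(fit)
  expect_identical(g$n, 10L)
  td <- tidy(fit)
  expect_setequal(td$term, c("lam", "k", "kappa", "x0", "y0"))
})

test_that("fitting is invariant to a constant rescaling with matching anchor", {
  p <- p_oscillatory()
  ser <- gen_recovery_series(p, noise_cv = 0.03, seed = 5)
  f1 <- fit_recovery(ser, n_starts = 8, seed = 2)
  scaled <- ser
  scaled$density <- ser$density * 37.5
  f2 <- fit_recovery(scaled, anchor = 37.5, n_starts = 8, seed = 2)
  expect_equal(f1$par, f2$par, tolerance = 1e-8)
})

test_that("a flat series triggers the unidentifiability warning and a trivial fit", {
  ser <- tibble::tibble(time_days = c(10, 20, 30, 40, 60, 90),
                        density = rep(1, 6))
  expect_warning(fit <- fit_recovery(ser, n_starts = 6, seed = 1), "unidentifiable")
  expect_true(fit$unidentifiable)
  expect_equal(fit$par[["x0"]], 1, tolerance = 0.05)
  expect_lt(fit$rss, 1e-6)
})

test_that("fitted trajectories settle at the genotype-specific steady state", {
  p <- p_oscillatory()
  ser <- gen_recovery_series(p, noise_cv = 0.02, seed = 7)
  fit <- fit_recovery(ser, n_starts = 8, seed = 3)
  far <- fitted_trajectory(fit, times = seq(0, 2000, 5))
  expect_equal(tail(far$s_rel, 1), 1, tolerance = 1e-3)
  # mutants with scaled supply also end at their own set point, for any
  # supply above the fit's critical ratio
  crit <- fit$par[["k"]] / (fit$par[["k"]] + fit$par[["kappa"]])
  for (sc in c(crit + 0.6 * (1 - crit), 1.3)) {
    mut <- predict_mutant(fit, sc, times = seq(0, 2000, 5))
    expect_false(attr(mut, "loss_state"))
    expect_equal(tail(mut$s_rel, 1), 1, tolerance = 1e-3)
  }
})

test_that("mutant prediction follows the linear dose law and flags the loss regime", {
  p <- p_oscillatory()
  ser <- gen_recovery_series(p, noise_cv = 0, seed = 1)
  fit <- fit_recovery(ser, n_starts = 16, seed = 1)
  # supply_scale = 1 reproduces the fitted trajectory
  tt <- seq(0, 110, 1)
  expect_equal(predict_mutant(fit, 1, times = tt)$s_rel,
               fitted_trajectory(fit, times = tt)$s_rel, tolerance = 1e-9)
  # mutant absolute set point scales linearly in the supply
  par <- fit$par
  for (sc in c(0.8, 1.5)) {
    x_star <- attr(predict_mutant(fit, sc, times = tt), "x_star_mut")
    expect_equal(x_star, (sc * (par[["k"]] + par[["kappa"]]) - par[["k"]]) / par[["kappa"]])
  }
  # below the critical ratio the mutant is predicted to collapse
  crit <- par[["k"]] / (par[["k"]] + par[["kappa"]])
  mut_loss <- predict_mutant(fit, 0.9 * crit, times = seq(0, 3000, 10))
  expect_true(attr(mut_loss, "loss_state"))
  expect_lt(tail(mut_loss$s_rel, 1), 1e-3)
  expect_error(predict_mutant(fit, -1), "> 0")
})

test_that("reduced supply changes the relative overshoot amplitude as the linearization predicts", {
  p <- p_oscillatory()
  ser <- gen_recovery_series(p, noise_cv = 0, seed = 1)
  fit <- fit_recovery(ser, n_starts = 16, seed = 1)
  tt <- seq(0, 300, 0.25)
  amp <- function(sc) {
    tr <- if (sc == 1) fitted_trajectory(fit, times = tt) else predict_mutant(fit, sc, times = tt)
    detect_oscillation(tibble::tibble(time = tr$time, s = tr$s_rel), 1)$first_peak_rel_amplitude
  }
  a_wt <- amp(1); a_lo <- amp(0.7)
  expect_false(is.na(a_wt)); expect_false(is.na(a_lo))
  expect_true(abs(a_lo - a_wt) > 1e-3)   # amplitude altered by supply change
})
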