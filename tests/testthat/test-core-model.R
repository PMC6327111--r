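test_that("fate law balances at c0 and is linear with slope lam/c0", {
  p <- kinetic_params(lam = 0.1)
  expect_identical(net_growth_rate(p$c0, p), 0)
  expect_equal(net_growth_rate(2 * p$c0, p), 0.1)
  expect_equal(net_growth_rate(0, p), -0.1)
  expect_error(net_growth_rate(-0.1, p), "non-negative")
  # strictly increasing
  cs <- seq(0, 3, 0.1)
  expect_true(all(diff(net_growth_rate(cs, p)) > 0))
  # duplication/loss split around beta, clipped at 0
  expect_equal(duplication_rate(p$c0, p), p$beta)
  expect_equal(loss_rate(p$c0, p), p$beta)
  expect_equal(duplication_rate(2, p) - loss_rate(2, p), net_growth_rate(2, p))
  plow <- suppressWarnings(kinetic_params(lam = 0.4, beta = 0.1))
  expect_identical(loss_rate(10, plow), 0)   # clipped, not negative
})

test_that("parameter validation enforces positivity and the beta >= lam/2 rule", {
  expect_error(kinetic_params(mu = -1), "positive")
  expect_error(kinetic_params(k = 0), "positive")
  expect_warning(kinetic_params(lam = 0.2, beta = 0.05), "clipped")
})

test_that("derivatives vanish at the fixed point and match direct substitution", {
  p <- kinetic_params(mu = 0.3, k = 0.1, kprime = 0.01, c0 = 1)
  s_star <- (p$mu - p$k * p$c0) / p$kprime
  expect_equal(unname(mito_derivatives(c(s = s_star, c = 1), p)), c(0, 0))
  # no cells: density inert, concentration relaxes to mu/k
  d0 <- mito_derivatives(c(s = 0, c = 2), p)
  expect_equal(unname(d0), c(0, p$mu - p$k * 2))
  # printed substitution example
  expect_equal(unname(mito_derivatives(c(s = 10, c = 1), p)), c(0, 0.1))
  expect_error(mito_derivatives(c(s = -1, c = 1), p), "non-negative")
})

test_that("steady state reproduces the closed form and the eigenvalue oracle", {
  p <- kinetic_params(mu = 0.3, k = 0.1, kprime = 0.01, c0 = 1)
  fp <- steady_state(p)
  expect_equal(unname(fp$homeostatic), c(20, 1))
  expect_equal(unname(fp$loss), c(0, 3))
  expect_equal(fp$critical_supply, 0.1)
  expect_true(fp$stable_homeostatic)
  expect_false(fp$stable_loss)
  # numeric eigenvalues against the hand-derived closed form
  for (p2 in list(p, p_oscillatory(), kinetic_params(mu = 0.5, k = 0.2, kprime = 0.03, c0 = 1.5))) {
    fp2 <- steady_state(p2)
    ev_oracle <- eigen_homeostatic_closed_form(p2)
    ev_num <- as.complex(fp2$eigen_homeostatic)
    expect_equal(sort(Re(ev_num)), sort(Re(ev_oracle)), tolerance = 1e-6)
    expect_equal(sort(abs(Im(ev_num))), sort(abs(Im(ev_oracle))), tolerance = 1e-6)
    expect_identical(fp2$oscillatory, any(abs(Im(ev_oracle)) > 1e-10))
    if (fp2$oscillatory) {
      expect_equal(fp2$damped_frequency, max(abs(Im(ev_oracle))), tolerance = 1e-6)
    }
  }
})

test_that("below the critical supply only the loss state exists and it is stable", {
  p <- kinetic_params(mu = 0.05, k = 0.1)
  fp <- steady_state(p)
  expect_null(fp$homeostatic)
  expect_true(fp$stable_loss)
  expect_equal(fp$loss[["c"]], 0.5)
  g <- glance(fp)
  expect_false(g$homeostatic_exists)
  # trajectories decay to the loss state
  traj <- simulate_density(p, init = c(s = 10, c = 1), times = seq(0, 800, 2))
  expect_lt(tail(traj$s, 1), 1e-6)
  expect_equal(tail(traj$c, 1), 0.5, tolerance = 1e-4)
})

test_that("simulation converges to the homeostatic state from arbitrary inits", {
  p <- p_default()
  fp <- steady_state(p)
  # constant at the fixed point
  traj0 <- simulate_density(p, init = fp$homeostatic, times = seq(0, 50, 1))
  expect_equal(traj0$s, rep(20, nrow(traj0)), tolerance = 1e-6)
  # far-from-equilibrium inits reach the same state
  t_grid <- seq(0, 600, 2)
  tr1 <- simulate_density(p, init = c(s = 2, c = 1), times = t_grid)
  tr2 <- simulate_density(p, init = c(s = 60, c = 0.2), times = t_grid)
  expect_equal(tail(tr1$s, 1), 20, tolerance = 1e-4)
  expect_equal(tail(tr1$c, 1), 1, tolerance = 1e-4)
  expect_equal(tail(tr2$s, 1), tail(tr1$s, 1), tolerance = 1e-4)
  expect_error(simulate_density(p, init = c(s = 1, c = 1), times = c(0, 0, 1)),
               "increasing")
})

test_that("fixed-point identity holds across random parameter draws", {
  withr::local_seed(20240901)
  for (i in 1:20) {
    p <- draw_params()
    fp <- steady_state(p)
    s_star <- fp$homeostatic[["s"]]
    init <- c(s = s_star * runif(1, 0.05, 3), c = p$c0 * runif(1, 0.2, 3))
    horizon <- 60 / abs(max(Re(fp$eigen_homeostatic)))
    traj <- simulate_density(p, init = init, times = seq(0, horizon, length.out = 400))
    expect_equal(tail(traj$s, 1) / s_star, 1, tolerance = 1e-4)
    expect_equal(tail(traj$c, 1) / p$c0, 1, tolerance = 1e-4)
  }
})

test_that("concentration is pinned at c0 so the net fate rate is supply-independent", {
  for (mu in c(0.15, 0.2, 0.25, 0.3, 1)) {
    p <- kinetic_params(mu = mu)
    fp <- steady_state(p)
    expect_equal(fp$homeostatic[["c"]], p$c0)
    expect_identical(net_growth_rate(fp$homeostatic[["c"]], p), 0)
  }
})

test_that("dose response is affine above threshold with slope 1/kprime", {
  p <- kinetic_params(k = 0.1, kprime = 0.01, c0 = 1)
  dr <- dose_response(p, c(0.15, 0.2, 0.25, 0.3))
  expect_equal(dr$s_star, c(5, 10, 15, 20))
  fitline <- lm(s_star ~ mu, data = dr)
  expect_lt(sum(residuals(fitline)^2), 1e-10)
  expect_equal(unname(coef(fitline)[2]), 1 / p$kprime)
  # threshold and linearity
  expect_equal(dose_response(p, 0.1)$s_star, 0)
  expect_equal(dose_response(p, 0.1 + 0.2)$s_star,
               2 * dose_response(p, 0.1 + 0.1)$s_star)
  expect_error(dose_response(p, numeric(0)), "non-empty")
})

test_that("tidy and glance summarise the fixed-point report", {
  fp <- steady_state(p_oscillatory())
  td <- tidy(fp)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$state, c("homeostatic", "loss"))
  g <- glance(fp)
  expect_true(g$oscillatory)
  expect_equal(g$damped_period, 2 * pi / fp$damped_frequency)
})
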