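test_that("binning follows the half-open 1-mm convention", {
  bc <- bin_counts(c(0.5, 1.5, 1.6), L = 3)
  expect_equal(bc$count, c(1, 2, 0))
  expect_equal(sum(bin_counts(runif(57, 0, 10), L = 10)$count), 57)
  expect_equal(bin_counts(numeric(0), L = 4)$count, rep(0L, 4))
  expect_equal(bin_counts(c(0, 3 - 1e-9), L = 3)$count, c(1, 0, 1))
  expect_error(bin_counts(c(-0.1), L = 3), "\\[0, L\\)")
  expect_error(bin_counts(0.5, L = 3.5), "divide")
})

test_that("source discretization conserves the total supply", {
  src <- source_map(position = c(3, 17.2, 40), width = c(0.25, 0.4, 0.25),
                    rate = c(1, 2.5, 0.7))
  prod <- mitocomp:::discretize_sources(src, L = 50, h = 0.05)
  expect_equal(sum(prod) * 0.05, sum(src$rate), tolerance = 1e-9)
  u <- mitocomp:::discretize_sources(uniform_sources(50, 0.3), L = 50, h = 0.05)
  expect_equal(u, rep(0.3, 1000))
})

test_that("configuration rejects unstable field steps", {
  expect_error(spatial_config(L = 10, h = 0.05, D_c = 10, dt_field = 1),
               "stability")
  expect_error(spatial_config(L = 10, h = 0.3), "divide")
})

test_that("runs are reproducible under a fixed seed and conserve field mass", {
  p <- p_default()
  sc <- spatial_config(L = 10, T = 10, seed = 5)
  src <- uniform_sources(10, 0.3)
  r1 <- run_spatial(sc, p, src, init_density = 20)
  r2 <- run_spatial(sc, p, src, init_density = 20)
  expect_identical(r1$final_positions, r2$final_positions)
  expect_identical(r1$population, r2$population)
  expect_lt(r1$mass_balance_err, 1e-8)
})

test_that("zero supply drives the population extinct", {
  p <- p_default()
  sc <- spatial_config(L = 10, T = 400, seed = 3)
  res <- run_spatial(sc, p, uniform_sources(10, 0), init_density = 10,
                     init_field = 0.5)
  expect_true(res$extinct)
  expect_length(res$final_positions, 0)
})

test_that("uniform production recovers the mean-field dynamics across seeds", {
  # population/L tracks s(t) of the deterministic model within MC error
  p <- p_default()
  L <- 20
  fp <- steady_state(p)
  t_probe <- c(20, 50, 80)
  mf <- simulate_density(p, init = c(s = 10, c = 1), times = seq(0, 80, 0.5))
  dens <- sapply(1:10, function(sd) {
    sc <- spatial_config(L = L, T = 80, seed = sd)
    res <- run_spatial(sc, p, uniform_sources(L, p$mu), init_density = 10,
                       checkpoint_times = t_probe)
    sapply(t_probe, function(tp) {
      res$population$density[which.min(abs(res$population$time - tp))]
    })
  })
  for (j in seq_along(t_probe)) {
    mf_s <- mf$s[which.min(abs(mf$time - t_probe[j]))]
    se <- sd(dens[j, ]) / sqrt(ncol(dens))
    expect_lt(abs(mean(dens[j, ]) - mf_s), 4 * se + 0.02 * mf_s)
  }
})

test_that("agent displacement is unbiased even in strong gradients", {
  # no chemotaxis: steps are symmetric regardless of the field
  p <- p_default()
  L <- 20
  sc <- spatial_config(L = L, T = 5, seed = 9)
  src <- source_map(position = 10, width = 0.25, rate = p$mu * L)
  res <- run_spatial(sc, p, src, init_density = 30, checkpoint_times = c(0.5, 5))
  first <- res$checkpoints$position[res$checkpoints$time < 1]
  last <- res$checkpoints$position[res$checkpoints$time >= 1]
  # mean signed displacement toward the source among survivors stays ~0:
  # compare mean distance change against the motility scale
  d1 <- mean(mitocomp:::periodic_distance(first, 10, L))
  d2 <- mean(mitocomp:::periodic_distance(last, 10, L))
  # drift would move the mean by >> sqrt(2 D_a t); tolerate sampling noise
  expect_lt(abs(d2 - d1), 0.6)
})

test_that("localized sources yield near-source enrichment and overdispersed counts", {
  p <- p_default()
  L <- 20
  sc <- spatial_config(L = L, T = 120, seed = 11)
  src <- source_map(position = c(0, 10), width = 0.25, rate = c(3, 3))
  res <- run_spatial(sc, p, src, init_density = 15)
  prof <- density_vs_distance(res, src, bin_width = 1)
  expect_gt(prof$density[1], tail(prof$density, 1))       # bin 0 vs farthest
  expect_gt(prof$density[prof$distance < 1][1],
            mean(prof$density[prof$distance >= 4]))
  # monotone trend: distance-density correlation strongly negative
  expect_lt(cor(prof$distance, prof$density, method = "spearman"), -0.5)
  # clustering emerges in 1-mm counts at stationarity
  last_cp <- res$checkpoints[res$checkpoints$time == max(res$checkpoints$time), ]
  vmr <- variance_to_mean(bin_counts(last_cp$position, L))
  expect_gt(vmr, 1)
})

test_that("a mitogen-soaked bead raises local density against a common-random-numbers control", {
  p <- p_default()
  L <- 20
  base <- uniform_sources(L, p$mu)
  sc <- spatial_config(L = L, T = 10, seed = 21)
  cps <- seq(4, 10, 1)
  ctrl <- run_spatial(sc, p, add_bead(base, 5, 0, 5), init_density = 20,
                      checkpoint_times = cps)
  bead <- run_spatial(sc, p, add_bead(base, 5, 2, 5), init_density = 20,
                      checkpoint_times = cps)
  plain <- run_spatial(sc, p, base, init_density = 20, checkpoint_times = cps)
  # zero-rate bead is the exact control under the same seed
  expect_identical(ctrl$final_positions, plain$final_positions)
  near <- function(r) sum(mitocomp:::periodic_distance(r$checkpoints$position, 5, L) <= 1)
  expect_gt(near(bead), near(ctrl))
  expect_error(add_bead(base, 5, 2, -1), "positive")
  expect_error(add_bead(base, 5, -2, 5), ">= 0")
})

test_that("density profile errors cleanly without checkpoints or localized sources", {
  p <- p_default()
  sc <- spatial_config(L = 10, T = 2, seed = 2)
  res <- run_spatial(sc, p, uniform_sources(10, 0.3), init_density = 10,
                     checkpoint_times = 1)
  expect_error(density_vs_distance(res, uniform_sources(10, 0.3)), "localized")
})
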