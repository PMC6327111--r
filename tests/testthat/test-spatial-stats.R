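test_that("variance-to-mean ratio uses the population-moment formula", {
  expect_equal(variance_to_mean(c(5, 5, 5, 5)), 0)
  expect_equal(variance_to_mean(c(1, 3)), 0.5)     # mean 2, population var 1
  expect_equal(variance_to_mean(c(1, 3), sample_variance = TRUE), 1)
  expect_error(variance_to_mean(c(0, 0, 0)), "zero")
  expect_error(variance_to_mean(c(1.5, 2)), "integer")
  # accepts binned_counts tibbles
  expect_equal(variance_to_mean(tibble::tibble(count = c(1, 3))), 0.5)
})

test_that("VMR converges to 1 for Poisson and to the target for clustered counts", {
  pois <- gen_clustered_counts(10000, mean = 8, vmr = 1, seed = 4)
  expect_equal(variance_to_mean(pois), 1, tolerance = 0.05)
  for (sd in 1:5) {
    nb <- gen_clustered_counts(10000, mean = 8, vmr = 3, seed = sd)
    expect_equal(variance_to_mean(nb), 3, tolerance = 0.1)
  }
})

test_that("Poisson goodness of fit pools tails and is calibrated under the null", {
  g <- poisson_gof(gen_clustered_counts(500, mean = 5, vmr = 1, seed = 2))
  expect_identical(g$df, g$n_cells - 2L)
  expect_gt(g$p_value, 0.001)
  # a degenerate spike is decisively non-Poisson
  expect_lt(suppressWarnings(poisson_gof(rep(5, 100))$p_value), 1e-10)
  expect_warning(poisson_gof(withr::with_seed(2, rpois(19, 5))), "fewer than 20")
  expect_error(poisson_gof(c(rep(0, 30))), "zero")
  # type-I error near nominal alpha over 200 null replicates
  rate <- withr::with_seed(1, {
    mean(sapply(1:200, function(i) poisson_gof(rpois(10000, 5))$p_value < 0.05))
  })
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("clustered counts at the homeostatic calibration reject Poisson decisively", {
  # the counted-tubule scale: 105 one-mm bins; a typical realization of the
  # clustered generator beats the reference bound by orders of magnitude
  ps <- vapply(1:10, function(sd) {
    poisson_gof(gen_clustered_counts(105, mean = 8, vmr = 3, seed = sd))$p_value
  }, numeric(1))
  expect_lt(median(ps), 1e-5)
  expect_true(all(ps < 0.05))
})

test_that("preference ratios and chi-square match hand-computed values", {
  # unbiased table: all preferences 1, p = 1
  tbl <- tibble::tibble(category = c("positive", "negative"),
                        length_fraction = c(0.4, 0.6), observed = c(4, 6))
  pr <- preference(tbl)
  expect_equal(pr$table$preference, c(1, 1))
  expect_equal(pr$statistic, 0)
  expect_equal(pr$p_value, 1)

  # biased table: hand-computed oracle, verified against stats::chisq.test
  tbl2 <- tibble::tibble(category = c("positive", "negative"),
                         length_fraction = c(0.5, 0.5), observed = c(8, 2))
  pr2 <- preference(tbl2)
  expect_equal(pr2$table$preference, c(1.6, 0.4))
  expect_equal(pr2$statistic, 3.6)
  expect_identical(pr2$df, 1L)
  ref <- suppressWarnings(stats::chisq.test(c(8, 2), p = c(0.5, 0.5)))
  expect_equal(pr2$statistic, unname(ref$statistic))
  expect_equal(pr2$p_value, ref$p.value)

  expect_error(preference(tibble::tibble(
    category = "a", length_fraction = 1, observed = 3
  )), "fractions")
  expect_error(preference(dplyr::mutate(tbl, observed = c(-1, 6))), ">= 0")
})

test_that("boundary cells are split half and half, conserving the total", {
  tbl <- tibble::tibble(category = c("positive", "negative"),
                        length_fraction = c(0.4, 0.6),
                        observed = c(3, 5), boundary_observed = c(2, 0))
  pr <- preference(tbl)
  expect_equal(pr$table$observed_adjusted, c(4, 6))
  expect_equal(sum(pr$table$observed_adjusted), 3 + 5 + 2)
  expect_equal(pr$table$preference, c(1, 1))
  # three categories with boundary counts are rejected
  tbl3 <- tibble::tibble(category = c("a", "b", "c"),
                         length_fraction = c(0.2, 0.3, 0.5),
                         observed = c(1, 2, 3), boundary_observed = c(1, 0, 0))
  expect_error(preference(tbl3), "two-category")
})

test_that("length-fraction-weighted preferences average to one", {
  withr::local_seed(11)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    f <- diff(c(0, sort(runif(k - 1)), 1))
    obs <- rmultinom(1, 50 + rpois(1, 50), runif(k))[, 1]
    if (any(obs == 0) || any(f < 0.02)) next
    pr <- preference(tibble::tibble(category = letters[1:k],
                                    length_fraction = f, observed = obs))
    expect_equal(sum(pr$table$length_fraction * pr$table$preference), 1)
  }
})

test_that("more than two categories are supported with df = k - 1", {
  tbl <- tibble::tibble(category = c("strong", "weak", "absent"),
                        length_fraction = c(0.2, 0.3, 0.5),
                        observed = c(30, 30, 40))
  pr <- preference(tbl)
  expect_identical(pr$df, 2L)
  ref <- stats::chisq.test(tbl$observed, p = tbl$length_fraction)
  expect_equal(pr$statistic, unname(ref$statistic))
  expect_equal(pr$p_value, ref$p.value)
})

test_that("the exact multinomial alternative agrees with binom.test at k = 2", {
  tbl <- tibble::tibble(category = c("positive", "negative"),
                        length_fraction = c(0.5, 0.5), observed = c(8, 2))
  pr <- preference(tbl, exact = TRUE)
  ref <- stats::binom.test(8, 10, 0.5)
  expect_equal(pr$p_value, ref$p.value)
})
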