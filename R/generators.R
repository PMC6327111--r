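#' Generate clustered per-bin counts
#'
#' Draws per-1-mm-bin counts with a prescribed mean and variance-to-mean
#' ratio, emulating the clustered arrangement of spermatogonial units along
#' the tubule (observed ratio about 3).  `vmr = 1` gives Poisson counts
#' (spatial randomness); `vmr > 1` gives negative-binomial counts with
#' size `mean / (vmr - 1)`, whose variance is exactly `mean * vmr`.
#'
#' @param n_bins Number of bins.
#' @param mean Mean count per bin (> 0).
#' @param vmr Target variance-to-mean ratio (>= 1; underdispersion is not
#'   supported).
#' @param seed RNG seed.
#' @param bin_width Bin width recorded in the output, mm.
#' @return A `binned_counts` tibble (`bin_start_mm`, `count`).
#' @examples
#' x <- gen_clustered_counts(1000, mean = 8, vmr = 3, seed = 1)
#' variance_to_mean(x)
#' @export
gen_clustered_counts <- function(n_bins, mean = 8, vmr = 3, seed = 1,
                                 bin_width = 1) {
  if (mean <= 0) abort("`mean` must be positive")
  if (vmr < 1) abort("`vmr` must be >= 1 (underdispersion unsupported)")
  cnt <- withr::with_seed(seed, {
    if (vmr == 1) {
      rpois(n_bins, mean)
    } else {
      rnbinom(n_bins, size = mean / (vmr - 1), mu = mean)
    }
  })
  structure(
    tibble::tibble(bin_start_mm = (seq_len(n_bins) - 1) * bin_width,
                   count = cnt),
    class = c("binned_counts", class(tibble::tibble())),
    bin_width = bin_width
  )
}

#' Default post-depletion sampling grid (days)
#'
#' The measurement days of the wild-type busulfan recovery experiment.
#' @export
recovery_day_grid <- function() c(10, 15, 20, 25, 30, 40, 50, 60, 80, 110)

#' Generate a synthetic recovery density series
#'
#' Depletes the homeostatic state by `depletion_fraction`, simulates the
#' mean-field model, samples the density (normalized to the homeostatic
#' set point) on the measurement-day grid, and applies independent
#' multiplicative lognormal noise of the given coefficient of variation
#' (positivity-preserving).
#'
#' @param params A [kinetic_params()] with a homeostatic state.
#' @param depletion_fraction Fraction of stem cells removed at t = 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param times Sampling days; default [recovery_day_grid()].
#' @param seed RNG seed.
#' @return Tibble with `time_days` and `density` (units of the homeostatic
#'   density).
#' @export
gen_recovery_series <- function(params, depletion_fraction = 0.9,
                                noise_cv = 0.1, times = recovery_day_grid(),
                                seed = 1) {
  params <- as_kinetic_params(params)
  if (depletion_fraction < 0 || depletion_fraction > 1) {
    abort("`depletion_fraction` must be in [0, 1]")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0")
  check_time_grid(times)
  fp <- steady_state(params)
  if (is.null(fp$homeostatic)) abort("parameters have no homeostatic state")
  s_star <- fp$homeostatic[["s"]]
  init <- deplete(fp$homeostatic, depletion_fraction)
  grid <- sort(unique(c(0, times)))
  traj <- simulate_density(params, init = init, times = grid)
  dens <- traj$s[match(times, traj$time)] / s_star
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- withr::with_seed(seed,
      rlnorm(length(dens), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    dens <- dens * noise
  }
  tibble::tibble(time_days = times, density = dens)
}

#' Generate a synthetic positional category table
#'
#' Places `total_cells` cells among positional categories with probability
#' proportional to length fraction times a per-category bias factor (all
#' bias 1 = the unbiased null), then independently relabels each cell as
#' "boundary" with probability `boundary_prob` (two-category tables only).
#' The expected preference of category i is
#' `bias_i / sum_j(fraction_j * bias_j)`.
#'
#' @param total_cells Number of cells to place (> 0).
#' @param length_fractions Circumference length fractions, summing to 1.
#' @param bias_factors Positive per-category bias factors.
#' @param boundary_prob Probability a placed cell is scored boundary.
#' @param seed RNG seed.
#' @param categories Category labels.
#' @return Tibble with `category`, `length_fraction`, `observed`,
#'   `boundary_observed` (boundary total carried on the first row).
#' @export
gen_category_table <- function(total_cells, length_fractions = c(0.4, 0.6),
                               bias_factors = c(1, 1), boundary_prob = 0,
                               seed = 1,
                               categories = paste0("cat", seq_along(length_fractions))) {
  if (total_cells <= 0) abort("`total_cells` must be positive")
  if (length(length_fractions) != length(bias_factors) ||
      length(length_fractions) != length(categories)) {
    abort("length_fractions, bias_factors and categories must align")
  }
  if (abs(sum(length_fractions) - 1) > 1e-9) abort("length fractions must sum to 1")
  if (any(bias_factors <= 0)) abort("bias factors must be positive")
  if (boundary_prob > 0 && length(length_fractions) != 2) {
    abort("boundary labelling supported only for two categories")
  }
  prob <- length_fractions * bias_factors
  prob <- prob / sum(prob)
  res <- withr::with_seed(seed, {
    cats <- drop(rmultinom(1, total_cells, prob))
    nb <- if (boundary_prob > 0) {
      sum(stats::rbinom(length(cats), cats, boundary_prob))
    } else 0L
    # boundary cells are removed proportionally from their categories
    if (nb > 0) {
      take <- drop(rmultinom(1, nb, cats / sum(cats)))
      while (any(take > cats)) {          # guard against overdraw
        excess <- pmax(take - cats, 0)
        take <- pmin(take, cats)
        room <- cats - take
        add <- drop(rmultinom(1, sum(excess), pmax(room, 1e-9)))
        take <- take + pmin(add, room)
      }
      cats <- cats - take
    }
    list(cats = cats, nb = nb)
  })
  boundary <- c(res$nb, rep(0L, length(categories) - 1))
  tibble::tibble(
    category = categories,
    length_fraction = length_fractions,
    observed = as.integer(res$cats),
    boundary_observed = as.integer(boundary)
  )
}

#' Generate a source map with renewal-process spacing
#'
#' Emulates vasculature-associated mitogen source regions: positions are
#' laid down along the periodic tubule with independent exponential gaps of
#' the given mean, all sources share the same width, and the per-source
#' rates are equal and sum to `total_supply` regardless of how many
#' sources were drawn.  If a draw yields no source inside the domain it is
#' retried (with a warning after many retries).
#'
#' @param L Domain length, mm.
#' @param mean_spacing Mean gap between sources, mm (< L).
#' @param width Gaussian bump width, mm.
#' @param total_supply Total integrated production, c0-units x mm / day.
#' @param seed RNG seed.
#' @return A [source_map()] tibble.
#' @export
gen_source_map <- function(L, mean_spacing, width = 0.25, total_supply,
                           seed = 1) {
  if (mean_spacing >= L) abort("`mean_spacing` must be smaller than L")
  pos <- withr::with_seed(seed, {
    p <- numeric(0)
    tries <- 0
    while (length(p) == 0) {
      tries <- tries + 1
      if (tries > 100) abort("failed to draw any source in 100 attempts")
      x <- runif(1, 0, mean_spacing)
      p <- numeric(0)
      while (x < L) {
        p <- c(p, x)
        x <- x + rexp(1, 1 / mean_spacing)
      }
      if (tries > 1 && length(p) > 0) {
        warn("source draw retried: first attempt produced an empty map")
      }
    }
    p
  })
  source_map(position = pos, width = width,
             rate = rep(total_supply / length(pos), length(pos)))
}
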