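#' Instantaneous fractional depletion of the stem pool
#'
#' Models a cytotoxic pulse (busulfan-like) as instantaneous removal of a
#' fraction of stem cells; the mitogen concentration is unchanged at the
#' moment of depletion, and subsequently accumulates because consumption
#' has dropped — the trigger of the recovery overshoot.
#'
#' @param state Named vector with `s` and `c` (optionally `d`).
#' @param fraction Fraction removed, in `[0, 1]`.  `d`, when present, is
#'   depleted by the same fraction.
#' @return State of the same shape with `s` (and `d`) scaled by
#'   `1 - fraction`.
#' @examples
#' deplete(c(s = 20, c = 1), 0.9)
#' @export
deplete <- function(state, fraction) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    abort("`fraction` must be in [0, 1]")
  }
  if (is.data.frame(state)) state <- unlist(state[1, ])
  state[["s"]] <- state[["s"]] * (1 - fraction)
  if ("d" %in% names(state)) state[["d"]] <- state[["d"]] * (1 - fraction)
  state
}

#' Detect overshoot and damped oscillations in a recovery trajectory
#'
#' Local extrema are located from sign changes of the first difference of
#' the (optionally smoothed) density series.  Overshoot is declared when
#' some local maximum exceeds the homeostatic density by more than
#' `epsilon` (relative); the damped period is the mean spacing of
#' successive local maxima and requires at least two of them.
#'
#' @param traj Trajectory data frame with columns `time` and `s` (a
#'   [simulate_density()] output, or any density series).
#' @param s_star Homeostatic reference density.
#' @param epsilon Relative overshoot threshold (default 0.02, suppressing
#'   numerical ripple).
#' @param smooth_window Centred moving-average window (points) applied
#'   before differencing; 1 disables smoothing.
#' @param ripple_tol Relative deviation from `s_star` below which an
#'   extremum is discarded as numerical ripple (flat-line artifacts near
#'   the set point).
#' @return One-row tibble of class `oscillation_report`: `overshoot`,
#'   `first_peak_time`, `first_peak_rel_amplitude` (peak/s* - 1),
#'   `period_days` (`NA` when fewer than 2 maxima), `n_extrema`,
#'   `period_defined`.
#' @export
detect_oscillation <- function(traj, s_star, epsilon = 0.02, smooth_window = 5,
                               ripple_tol = 1e-5) {
  t <- traj$time; y <- traj$s
  if (length(t) < 5) abort("trajectory too short")
  if (!is.finite(s_star) || s_star <= 0) abort("`s_star` must be positive")
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    ys <- stats::filter(y, k, sides = 2)
    pad <- is.na(ys)
    ys[pad] <- y[pad]
  } else {
    ys <- y
  }
  dy <- diff(ys)
  sgn <- sign(dy)
  sgn[sgn == 0] <- 1
  turn <- which(diff(sgn) != 0) + 1
  maxima <- turn[sgn[turn - 1] > 0]
  minima <- turn[sgn[turn - 1] < 0]
  # refine each maximum on the raw series within the smoothing window
  refine <- function(i) {
    lo <- max(1L, i - as.integer(smooth_window))
    hi <- min(length(y), i + as.integer(smooth_window))
    lo + which.max(y[lo:hi]) - 1L
  }
  maxima <- unique(vapply(as.integer(maxima), refine, integer(1)))
  # drop extrema indistinguishable from the set point (numerical ripple)
  keep <- abs(y[maxima] - s_star) > ripple_tol * s_star
  maxima <- maxima[keep]
  minima <- minima[abs(y[minima] - s_star) > ripple_tol * s_star]
  peaks_above <- maxima[y[maxima] > s_star * (1 + epsilon)]
  overshoot <- length(peaks_above) > 0
  first_peak_time <- if (overshoot) t[peaks_above[1]] else NA_real_
  first_peak_amp <- if (overshoot) y[peaks_above[1]] / s_star - 1 else NA_real_
  period <- NA_real_
  if (length(maxima) >= 2) period <- mean(diff(t[maxima]))
  structure(
    tibble::tibble(
      overshoot = overshoot,
      first_peak_time = first_peak_time,
      first_peak_rel_amplitude = first_peak_amp,
      period_days = period,
      n_extrema = length(maxima) + length(minima),
      period_defined = length(maxima) >= 2
    ),
    class = c("oscillation_report", class(tibble::tibble()))
  )
}

# --- nondimensional recovery model -----------------------------------------
#
# x = s/s*, y = c/c0; the supply is pinned by homeostasis, mu~ = k + kappa
# with kappa = kprime * s* / c0, leaving three rate parameters:
#   dx/dt = lam (y - 1) x
#   dy/dt = (k + kappa) - k y - kappa x y

rhs_nondim <- function(t, st, p) {
  x <- max(st[[1]], 0); y <- max(st[[2]], 0)
  list(c(
    p[["lam"]] * (y - 1) * x,
    (p[["k"]] + p[["kappa"]]) - p[["k"]] * y - p[["kappa"]] * x * y
  ))
}

solve_nondim <- function(lam, k, kappa, x0, y0, times, mu_nd = k + kappa,
                         dt_max = 0.05) {
  m <- nondim_rk4_cpp(lam, k, kappa, x0, y0, mu_nd, times, dt_max)
  data.frame(time = times, x = m[, 1], y = m[, 2])
}

default_fit_bounds <- function() {
  list(
    lam = c(0.005, 1), k = c(0.005, 1), kappa = c(0.005, 2),
    x0 = c(1e-3, 1.5), y0 = c(0.2, 5)
  )
}

# logit-style map between the box and the real line (derivative-free search
# runs unconstrained)
to_unconstrained <- function(p, bounds) {
  q <- (p - sapply(bounds, `[`, 1)) / (sapply(bounds, `[`, 2) - sapply(bounds, `[`, 1))
  q <- pmin(pmax(q, 1e-9), 1 - 1e-9)
  stats::qlogis(q)
}
from_unconstrained <- function(z, bounds) {
  lo <- sapply(bounds, `[`, 1); hi <- sapply(bounds, `[`, 2)
  lo + (hi - lo) * stats::plogis(z)
}

#' Fit the mean-field model to a recovery time series
#'
#' Least-squares fit of the nondimensionalized model (density measured in
#' units of its homeostatic set point, concentration in units of `c0`) to a
#' post-depletion density series.  The free parameters are the three rates
#' `lam` (fate sensitivity), `k` (mitogen decay) and
#' `kappa = kprime * s_star / c0` (homeostatic consumption), plus the
#' initial condition `x0 = s(0)/s*`, `y0 = c(0)/c0`; the supply rate is
#' pinned by homeostasis (`mu/c0 = k + kappa`).  The objective is the sum
#' of squared residuals of `s(t_i)/s*` against the data (inverse-variance
#' weighted when a `sem` column is present), minimized by derivative-free
#' bounded local search (Nelder-Mead on a logit-transformed box) from
#' `n_starts` Latin-hypercube starting points; the best start wins and the
#' spread across starts is reported as a multimodality diagnostic.
#'
#' @param data Data frame with columns `time_days` (or `time`) and
#'   `density`, optionally `sem`.  Densities may be absolute or already
#'   normalized; when `anchor` (the pre-treatment density) is supplied the
#'   series is divided by it, otherwise it is assumed normalized.
#' @param anchor Optional pre-treatment (homeostatic) density used to
#'   normalize absolute series.
#' @param bounds Named list of `c(lo, hi)` for `lam`, `k`, `kappa`, `x0`,
#'   `y0`; see `default_fit_bounds()`.
#' @param n_starts Number of Latin-hypercube multistarts.
#' @param seed RNG seed controlling the multistart design (deterministic).
#' @return Object of class `mito_fit`: fitted parameters, RSS, convergence
#'   flag, per-start results, a flat-series identifiability warning flag,
#'   and the data.  Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_recovery <- function(data, anchor = NULL, bounds = default_fit_bounds(),
                         n_starts = 32, seed = 1) {
  tcol <- if ("time_days" %in% names(data)) "time_days" else "time"
  if (!tcol %in% names(data) || !"density" %in% names(data)) {
    abort("`data` needs columns time_days (or time) and density")
  }
  times <- data[[tcol]]
  dens <- data[["density"]]
  if (length(times) < 6) abort("need at least 6 time points")
  if (any(diff(times) <= 0) || any(times < 0)) abort("times must be non-negative and increasing")
  if (any(dens < 0)) abort("densities must be non-negative")
  if (!is.null(anchor)) {
    if (anchor <= 0) abort("`anchor` must be positive")
    dens <- dens / anchor
  }
  w <- if ("sem" %in% names(data) && !is.null(anchor)) {
    (anchor / data[["sem"]])^2
  } else if ("sem" %in% names(data)) {
    1 / data[["sem"]]^2
  } else {
    rep(1, length(dens))
  }
  w <- w / mean(w)

  flat <- stats::sd(dens) < 1e-3 * max(mean(dens), 1e-12)
  if (flat) {
    warn("series is flat: lam is unidentifiable; fit reports the trivial steady solution")
  }

  obj <- function(z) {
    p <- from_unconstrained(z, bounds)
    sol <- try(
      solve_nondim(p[["lam"]], p[["k"]], p[["kappa"]], p[["x0"]], p[["y0"]], times),
      silent = TRUE
    )
    if (inherits(sol, "try-error") || any(!is.finite(sol$x))) return(1e6)
    sum(w * (sol$x - dens)^2)
  }

  nm <- names(default_fit_bounds())
  starts <- withr::with_seed(seed, lhs::randomLHS(n_starts, length(nm)))
  colnames(starts) <- nm
  # seed one start from the data itself: x0 ~ first point, y0 ~ 1
  lo <- sapply(bounds, `[`, 1); hi <- sapply(bounds, `[`, 2)
  guess <- c(lam = 0.15, k = 0.08, kappa = 0.3,
             x0 = min(max(dens[1], lo[["x0"]]), hi[["x0"]]), y0 = 1)
  starts[1, ] <- (pmin(pmax(guess[nm], lo + 1e-6), hi - 1e-6) - lo) / (hi - lo)

  runs <- lapply(seq_len(n_starts), function(i) {
    p0 <- lo + (hi - lo) * starts[i, ]
    z0 <- to_unconstrained(p0, bounds)
    fit <- try(
      stats::optim(z0, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) return(NULL)
    list(par = from_unconstrained(fit$par, bounds), value = fit$value,
         convergence = fit$convergence)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) abort("all multistarts failed")
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  # polish the winner
  zb <- to_unconstrained(best$par, bounds)
  pol <- stats::optim(zb, obj, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-14))
  if (pol$value <= best$value) {
    best <- list(par = from_unconstrained(pol$par, bounds), value = pol$value,
                 convergence = pol$convergence)
  }
  # convergence check: a fresh restart from the optimum that cannot improve
  # the objective materially counts as converged (NM's own maxit code is
  # uninformative once reltol sits at rounding level)
  re <- stats::optim(to_unconstrained(best$par, bounds), obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  converged <- best$convergence == 0 || re$convergence == 0 ||
    (best$value - re$value) <= max(1e-8 * best$value, 1e-12)
  if (re$value < best$value) {
    best <- list(par = from_unconstrained(re$par, bounds), value = re$value,
                 convergence = re$convergence)
  }

  structure(
    list(
      par = best$par,
      rss = best$value,
      convergence = converged,
      multistart_rss = sort(vals),
      multistart_dispersion = stats::sd(vals) / max(min(vals), .Machine$double.eps),
      unidentifiable = flat,
      data = tibble::tibble(time_days = times, density = dens, weight = w),
      bounds = bounds,
      n_starts = n_starts,
      seed = seed
    ),
    class = "mito_fit"
  )
}

#' @export
print.mito_fit <- function(x, ...) {
  cat("<mito_fit>\n")
  cat(sprintf(
    "  lam = %.4g /d, k = %.4g /d, kappa = %.4g /d\n  x0 = s(0)/s* = %.4g, y0 = c(0)/c0 = %.4g\n",
    x$par[["lam"]], x$par[["k"]], x$par[["kappa"]], x$par[["x0"]], x$par[["y0"]]
  ))
  cat(sprintf("  RSS = %.4g over %d points; converged: %s\n",
              x$rss, nrow(x$data), x$convergence))
  if (x$unidentifiable) cat("  note: flat series, lam unidentifiable\n")
  invisible(x)
}

#' @export
tidy.mito_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$par),
    estimate = unname(x$par),
    lower = vapply(x$bounds[names(x$par)], `[`, numeric(1), 1),
    upper = vapply(x$bounds[names(x$par)], `[`, numeric(1), 2)
  )
}

#' @export
glance.mito_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, n = nrow(x$data), converged = x$convergence,
    multistart_dispersion = x$multistart_dispersion,
    unidentifiable = x$unidentifiable
  )
}

#' Fitted recovery trajectory on a fine grid
#'
#' @param fit A `mito_fit` object.
#' @param times Evaluation grid, days; defaults to a fine grid over the data.
#' @param supply_scale Optional multiplicative rescaling of the supply rate
#'   (see [predict_mutant()]).
#' @return Tibble with `time`, `s_rel` (density over its own steady state),
#'   `c_rel`.
#' @export
fitted_trajectory <- function(fit, times = NULL, supply_scale = 1) {
  stopifnot(inherits(fit, "mito_fit"))
  if (is.null(times)) {
    times <- seq(0, max(fit$data$time_days), by = 0.25)
  }
  p <- fit$par
  if (supply_scale == 1) {
    sol <- solve_nondim(p[["lam"]], p[["k"]], p[["kappa"]], p[["x0"]], p[["y0"]], times)
    return(tibble::tibble(time = times, s_rel = sol$x, c_rel = sol$y))
  }
  predict_mutant(fit, supply_scale, times = times)
}

#' Predict recovery of a supply-rate mutant
#'
#' Re-simulates the fitted model with the mitogen supply scaled by
#' `supply_scale` (genetics: supply proportional to mitogen gene dosage),
#' all other rates fixed, and re-normalizes the density to the mutant's own
#' homeostatic set point, which follows the linear dose law
#' `x_star_mut = (scale * (k + kappa) - k) / kappa` in units of the
#' wild-type set point.  The initial condition keeps the same depletion
#' fraction relative to the mutant's own steady state.
#'
#' @param fit A converged `mito_fit`.
#' @param supply_scale Positive multiplier of the supply rate.
#' @param times Evaluation grid, days.
#' @return Tibble with `time`, `s_rel` (density / mutant steady state),
#'   `c_rel`; attribute `loss_state` flags `supply_scale` below the
#'   critical ratio (mutant pinned to extinction), in which case densities
#'   are relative to the wild-type set point instead.
#' @export
predict_mutant <- function(fit, supply_scale, times = NULL) {
  stopifnot(inherits(fit, "mito_fit"))
  if (!is.finite(supply_scale) || supply_scale <= 0) abort("`supply_scale` must be > 0")
  if (!fit$convergence) abort("fit did not converge")
  if (is.null(times)) times <- seq(0, max(fit$data$time_days), by = 0.25)
  p <- fit$par
  mu_wt <- p[["k"]] + p[["kappa"]]          # nondimensional supply, wt units
  mu_mut <- supply_scale * mu_wt
  x_star_mut <- (mu_mut - p[["k"]]) / p[["kappa"]]  # in wt s* units
  loss <- x_star_mut <= 0
  # dynamics in wt units with rescaled supply: dy/dt = mu_mut - k y - kappa x y
  x0 <- if (loss) p[["x0"]] else p[["x0"]] * x_star_mut
  sol <- solve_nondim(p[["lam"]], p[["k"]], p[["kappa"]], x0, p[["y0"]],
                      times, mu_nd = mu_mut)
  denom <- if (loss) 1 else x_star_mut
  structure(
    tibble::tibble(time = times, s_rel = sol$x / denom, c_rel = sol$y),
    loss_state = loss, x_star_mut = x_star_mut
  )
}
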