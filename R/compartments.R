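#' Time derivatives of the two-compartment model
#'
#' Stem cells `S` and differentiation-destined progenitors `D` compete for
#' the same mitogen pool:
#' \deqn{ds/dt = [r(c) - \delta] s + \omega d}
#' \deqn{dd/dt = \ell(c) s - (\gamma + \omega) d}
#' \deqn{dc/dt = \mu - k c - (k' s + k'_d d)(c/c_0)}
#' Progenitors are produced by the loss channel of the stem compartment
#' (differentiation = exit from S into D, flux `ell(c) s` clipped at zero)
#' and leave at rate `gamma`; reversion `omega` and stem death `delta` are
#' small optional perturbations.  The stem equation uses the net fate rate
#' `r(c)` (equal to `alpha(c) - ell(c)` wherever neither is clipped), so
#' with `omega = delta = kprime_d = 0` the `(s, c)` subsystem reduces
#' exactly to [mito_derivatives()].
#'
#' @param state Named numeric vector or one-row data frame with `s`, `d`,
#'   `c`, all non-negative.
#' @param params An [extended_params()] object.
#' @return Named numeric vector `c(ds_dt, dd_dt, dc_dt)`.
#' @export
mito_derivatives2 <- function(state, params) {
  stopifnot(inherits(params, "extended_params"))
  if (is.data.frame(state)) state <- unlist(state[1, c("s", "d", "c")])
  s <- state[["s"]]; d <- state[["d"]]; cc <- state[["c"]]
  if (any(!is.finite(c(s, d, cc))) || any(c(s, d, cc) < 0)) {
    abort("state components s, d, c must be finite and non-negative")
  }
  b <- params$base
  # net stem growth uses the net fate rate (alpha - ell before clipping) so
  # the omega = delta = kprime_d = 0 reduction is exact; the flux into D is
  # a physical event rate and is clipped at zero
  r <- net_growth_rate(cc, b)
  ell <- loss_rate(cc, b)
  c(
    ds_dt = (r - params$delta) * s + params$omega * d,
    dd_dt = ell * s - (params$gamma + params$omega) * d,
    dc_dt = b$mu - b$k * cc - (b$kprime * s + params$kprime_d * d) * (cc / b$c0)
  )
}

rhs_two_pool <- function(t, y, params) {
  st <- c(s = max(y[[1]], 0), d = max(y[[2]], 0), c = max(y[[3]], 0))
  list(unname(mito_derivatives2(st, params)))
}

#' Effective consumption rate of the reduced one-compartment model
#'
#' With no reversion or stem death, the progenitor compartment reaches a
#' slaved quasi-steady state `d = ell(c) s / gamma`, so its consumption
#' renormalizes the stem consumption rate:
#' `kprime_eff = kprime + kprime_d * beta / gamma`, and the two-compartment
#' homeostatic stem density is `(mu - k*c0) / kprime_eff`.  This mapping is
#' exact only for `omega = delta = 0`; otherwise the same expression is
#' returned with `exact = FALSE` as a first-order approximation.
#'
#' @param params An [extended_params()] object.
#' @return A numeric scalar with attribute `exact` (logical).
#' @examples
#' p <- extended_params(kinetic_params(beta = 0.03), gamma = 0.06)
#' effective_consumption(p)  # 1.5 * kprime
#' @export
effective_consumption <- function(params) {
  stopifnot(inherits(params, "extended_params"))
  b <- params$base
  keff <- b$kprime + params$kprime_d * b$beta / params$gamma
  exact <- params$omega == 0 && params$delta == 0
  if (!exact) {
    warn("effective consumption mapping is exact only for omega = delta = 0; returning the omega = delta = 0 approximation")
  }
  structure(keff, exact = exact)
}

#' Analytic homeostatic state of the two-compartment model (omega = delta = 0)
#'
#' @param params An [extended_params()] object with `omega = delta = 0`.
#' @return Named vector `c(s, d, c)`.
#' @export
steady_state2 <- function(params) {
  stopifnot(inherits(params, "extended_params"))
  if (params$omega != 0 || params$delta != 0) {
    abort("closed-form steady state implemented only for omega = delta = 0; use simulate_two_pool()")
  }
  b <- params$base
  keff <- as.numeric(effective_consumption(params))
  s_star <- (b$mu - b$k * b$c0) / keff
  if (s_star <= 0) abort("mu <= k*c0: no homeostatic state")
  c(s = s_star, d = b$beta * s_star / params$gamma, c = b$c0)
}

#' Simulate the two-compartment model
#'
#' @inheritParams simulate_density
#' @param params An [extended_params()] object.
#' @param init Named vector `c(s = , d = , c = )`; defaults to the analytic
#'   homeostatic state when `omega = delta = 0`.
#' @return A tibble of class `mito_trajectory` with columns `time`, `s`,
#'   `d`, `c`.
#' @export
simulate_two_pool <- function(params, init = NULL, times = seq(0, 200, by = 0.5),
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "extended_params"))
  check_time_grid(times)
  if (is.null(init)) init <- steady_state2(params)
  if (is.data.frame(init)) init <- unlist(init[1, c("s", "d", "c")])
  init <- c(s = init[["s"]], d = init[["d"]], c = init[["c"]])
  if (any(!is.finite(init)) || any(init < 0)) abort("init must be non-negative and finite")
  sol <- deSolve::ode(
    y = init, times = times, func = rhs_two_pool, parms = params,
    method = "lsoda", rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    abort(paste("ODE solver failed; istate =", attr(sol, "istate")[1]))
  }
  out <- tibble::tibble(
    time = sol[, "time"],
    s = pmax(sol[, "s"], 0),
    d = pmax(sol[, "d"], 0),
    c = pmax(sol[, "c"], 0)
  )
  new_trajectory(out, params = params, extinct = FALSE)
}

#' Phase lag between stem and progenitor oscillations
#'
#' Estimates how far the progenitor density series lags the stem density
#' series during oscillatory recovery, as the argmax of the normalized
#' cross-correlation of the two linearly detrended, mean-subtracted series,
#' cubic-interpolated onto a 0.1-day grid.  A positive lag means `d` peaks
#' after `s`, the ordering expected when progenitors are fed by stem cell
#' differentiation.  When neither series shows a detectable oscillation
#' (relative fluctuation below `min_amplitude`) the lag is undefined.
#'
#' @param data Data frame with time and the two density series.
#' @param time,s,d Column names (strings).
#' @param max_lag Largest lag scanned, days; defaults to half the dominant
#'   oscillation period (estimated from the autocorrelation of the
#'   detrended stem series), which removes the whole-period aliases of the
#'   cross-correlation; falls back to a third of the span when no period
#'   is detectable.
#' @param min_amplitude Minimum detrended fluctuation (relative to the
#'   series mean) for an oscillation to count as detected.
#' @return One-row tibble with `lag_days`, `defined`, `peak_correlation`.
#' @export
phase_lag <- function(data, time = "time", s = "s", d = "d",
                      max_lag = NULL, min_amplitude = 0.01) {
  t <- data[[time]]; sv <- data[[s]]; dv <- data[[d]]
  if (length(t) < 5) abort("need at least 5 time points")
  grid <- seq(min(t), max(t), by = 0.1)
  detrend <- function(y) {
    yi <- stats::spline(t, y, xout = grid)$y
    r <- stats::lm.fit(cbind(1, grid), yi)$residuals
    r
  }
  rs <- detrend(sv); rd <- detrend(dv)
  amp_s <- stats::sd(rs) / max(mean(abs(sv)), .Machine$double.eps)
  amp_d <- stats::sd(rd) / max(mean(abs(dv)), .Machine$double.eps)
  if (amp_s < min_amplitude || amp_d < min_amplitude) {
    return(tibble::tibble(lag_days = NA_real_, defined = FALSE,
                          peak_correlation = NA_real_))
  }
  if (is.null(max_lag)) {
    # dominant period from the first positive-lag peak of the
    # autocorrelation of the detrended stem series
    ac <- stats::acf(rs, lag.max = length(rs) - 1, plot = FALSE)$acf[, 1, 1]
    neg <- which(ac < 0)
    per <- NA_real_
    if (length(neg)) {
      after <- ac[neg[1]:length(ac)]
      turns <- which(diff(sign(diff(after))) < 0) + 1
      turns <- turns[after[turns] > 0.05]
      if (length(turns)) per <- (neg[1] + turns[1] - 2) * 0.1
    }
    max_lag <- if (is.finite(per)) per / 2 else (max(t) - min(t)) / 3
  }
  lags <- seq(0, max_lag, by = 0.1)
  lags <- c(-rev(lags[-1]), lags)   # symmetric grid through 0
  n <- length(grid)
  cc <- vapply(lags, function(L) {
    k <- round(L / 0.1)
    if (k >= 0) {
      a <- rs[seq_len(n - k)]; b <- rd[seq_len(n - k) + k]
    } else {
      a <- rs[seq_len(n + k) - k]; b <- rd[seq_len(n + k)]
    }
    if (length(a) < 10 || stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  best <- max(cc)
  # ties (within numerical noise) broken toward the smallest |lag|
  cand <- lags[cc >= best - 1e-12]
  lag <- cand[which.min(abs(cand))]
  tibble::tibble(lag_days = lag, defined = TRUE, peak_correlation = best)
}
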