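#' Concentration-dependent fate rates
#'
#' The net per-cell growth rate of the stem compartment is linear in the
#' mitogen concentration, `r(c) = lam * (c - c0) / c0`: it vanishes exactly
#' at the threshold `c0`, is positive above it (duplication outweighs loss)
#' and negative below.  `duplication_rate()` and `loss_rate()` split the net
#' rate around the baseline turnover `beta` as `beta + r/2` and `beta - r/2`,
#' clipped at zero so they remain valid event rates at extreme
#' concentrations.
#'
#' @param c Mitogen concentration (c0 units), non-negative; vectorized.
#' @param params A [kinetic_params()] object.
#' @return Rate(s), per day.
#' @examples
#' p <- kinetic_params(lam = 0.1)
#' net_growth_rate(c(0, 1, 2), p)
#' @export
net_growth_rate <- function(c, params) {
  params <- as_kinetic_params(params)
  if (any(!is.finite(c)) || any(c < 0)) {
    abort("concentration must be finite and non-negative")
  }
  params$lam * (c - params$c0) / params$c0
}

#' @rdname net_growth_rate
#' @export
duplication_rate <- function(c, params) {
  params <- as_kinetic_params(params)
  pmax(0, params$beta + net_growth_rate(c, params) / 2)
}

#' @rdname net_growth_rate
#' @export
loss_rate <- function(c, params) {
  params <- as_kinetic_params(params)
  pmax(0, params$beta - net_growth_rate(c, params) / 2)
}

#' Time derivatives of the mean-field model
#'
#' The coupled dynamics of stem cell density `s` and mitogen concentration
#' `c`:
#' \deqn{ds/dt = r(c)\,s, \qquad dc/dt = \mu - k c - k' s\,(c/c_0),}
#' with `r(c)` the linear net growth rate of [net_growth_rate()].  The
#' consumption term is proportional to `c` so that the flux vanishes when no
#' mitogen is present; at `c = c0` it reduces to `kprime * s`, which fixes
#' the homeostatic state at `s* = (mu - k*c0)/kprime`, `c* = c0`.
#'
#' @param state Named numeric vector or one-row data frame with components
#'   `s` (cells/mm) and `c` (c0 units), both non-negative.
#' @param params A [kinetic_params()] object.
#' @return Named numeric vector `c(ds_dt, dc_dt)`.
#' @examples
#' p <- kinetic_params()
#' mito_derivatives(c(s = 20, c = 1), p)  # the fixed point: both zero
#' @export
mito_derivatives <- function(state, params) {
  params <- as_kinetic_params(params)
  if (is.data.frame(state)) state <- unlist(state[1, c("s", "c")])
  s <- state[["s"]]; cc <- state[["c"]]
  if (!is.finite(s) || !is.finite(cc) || s < 0 || cc < 0) {
    abort("state components s and c must be finite and non-negative")
  }
  c(
    ds_dt = net_growth_rate(cc, params) * s,
    dc_dt = params$mu - params$k * cc - params$kprime * s * (cc / params$c0)
  )
}

# rhs in deSolve's signature; clips tiny negative excursions so that the
# fate law's domain check never trips inside the integrator
rhs_core <- function(t, y, params) {
  s <- max(y[[1]], 0); cc <- max(y[[2]], 0)
  r <- params$lam * (cc - params$c0) / params$c0
  list(c(
    r * s,
    params$mu - params$k * cc - params$kprime * s * (cc / params$c0)
  ))
}

#' Fixed points and stability of the mean-field model
#'
#' The model always possesses a loss state `(s, c) = (0, mu/k)`; above the
#' critical supply rate `mu_c = k * c0` a homeostatic state appears at
#' `s* = (mu - k*c0)/kprime`, `c* = c0`.  Stability is read off the
#' eigenvalues of the 2x2 Jacobian, evaluated numerically at each fixed
#' point; the homeostatic point is reported oscillatory when its
#' eigenvalues form a complex-conjugate pair, in which case the damped
#' angular frequency (|Im lambda|, rad/day) is returned.
#'
#' @param params A [kinetic_params()] object.
#' @return An object of class `mito_fixed_points` with elements
#'   `homeostatic` (named vector or `NULL` when `mu <= k*c0`), `loss`,
#'   `eigen_homeostatic`, `eigen_loss`, `stable_homeostatic`,
#'   `stable_loss`, `oscillatory`, `damped_frequency` (rad/day or `NA`),
#'   and `critical_supply`.  Has [tidy()] and [glance()] methods.
#' @examples
#' steady_state(kinetic_params(mu = 0.3, k = 0.1, kprime = 0.01))
#' @export
steady_state <- function(params) {
  params <- as_kinetic_params(params)
  mu_c <- params$k * params$c0
  loss <- c(s = 0, c = params$mu / params$k)

  jac_at <- function(pt) {
    pracma::jacobian(
      function(y) unname(mito_derivatives(c(s = max(y[1], 0), c = max(y[2], 0)), params)),
      unname(pt)
    )
  }
  ev_loss <- eigen(jac_at(loss), only.values = TRUE)$values

  homeo <- NULL
  ev_h <- NULL
  oscillatory <- FALSE
  damped_freq <- NA_real_
  if (params$mu > mu_c) {
    homeo <- c(s = (params$mu - mu_c) / params$kprime, c = params$c0)
    ev_h <- eigen(jac_at(homeo), only.values = TRUE)$values
    oscillatory <- is.complex(ev_h) && any(abs(Im(ev_h)) > 1e-10)
    if (oscillatory) damped_freq <- max(abs(Im(ev_h)))
  }

  structure(
    list(
      homeostatic = homeo,
      loss = loss,
      eigen_homeostatic = ev_h,
      eigen_loss = ev_loss,
      stable_homeostatic = if (is.null(ev_h)) NA else all(Re(ev_h) < 0),
      stable_loss = all(Re(ev_loss) < 0),
      oscillatory = oscillatory,
      damped_frequency = damped_freq,
      critical_supply = mu_c,
      params = params
    ),
    class = "mito_fixed_points"
  )
}

#' @export
print.mito_fixed_points <- function(x, ...) {
  cat("<mito_fixed_points>\n")
  cat(sprintf("  critical supply mu_c = %g /d (mu = %g)\n",
              x$critical_supply, x$params$mu))
  if (is.null(x$homeostatic)) {
    cat("  homeostatic state: absent (mu <= k*c0)\n")
  } else {
    cat(sprintf("  homeostatic state: s* = %g cells/mm, c* = %g (%s%s)\n",
                x$homeostatic[["s"]], x$homeostatic[["c"]],
                if (isTRUE(x$stable_homeostatic)) "stable" else "unstable",
                if (x$oscillatory)
                  sprintf(", oscillatory, omega = %.4g rad/d", x$damped_frequency)
                else ""))
  }
  cat(sprintf("  loss state: s = 0, c = %g (%s)\n", x$loss[["c"]],
              if (x$stable_loss) "stable" else "unstable"))
  invisible(x)
}

#' @export
tidy.mito_fixed_points <- function(x, ...) {
  rows <- list(
    tibble::tibble(
      state = "loss", s = x$loss[["s"]], c = x$loss[["c"]],
      stable = x$stable_loss,
      re_eigen_max = max(Re(x$eigen_loss)),
      im_eigen_max = max(abs(Im(x$eigen_loss)))
    )
  )
  if (!is.null(x$homeostatic)) {
    rows <- c(list(
      tibble::tibble(
        state = "homeostatic",
        s = x$homeostatic[["s"]], c = x$homeostatic[["c"]],
        stable = x$stable_homeostatic,
        re_eigen_max = max(Re(x$eigen_homeostatic)),
        im_eigen_max = max(abs(Im(x$eigen_homeostatic)))
      )
    ), rows)
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.mito_fixed_points <- function(x, ...) {
  tibble::tibble(
    critical_supply = x$critical_supply,
    homeostatic_exists = !is.null(x$homeostatic),
    s_star = if (is.null(x$homeostatic)) NA_real_ else x$homeostatic[["s"]],
    oscillatory = x$oscillatory,
    damped_frequency = x$damped_frequency,
    damped_period = if (is.na(x$damped_frequency)) NA_real_ else 2 * pi / x$damped_frequency
  )
}

#' Simulate the mean-field model
#'
#' Adaptive-step integration (lsoda) of the coupled density/concentration
#' dynamics, evaluated on a user grid.  States are clipped at zero; if the
#' stem density falls below `extinction_tol` times the homeostatic density
#' (or below `extinction_tol` cells/mm when no homeostatic state exists)
#' the trajectory is flagged as having reached the loss basin.
#'
#' @param params A [kinetic_params()] object.
#' @param init Named vector `c(s = , c = )`; defaults to the homeostatic
#'   state when it exists.
#' @param times Strictly increasing non-negative time grid, days.
#' @param rtol,atol Integration tolerances.
#' @param extinction_tol Relative threshold for the extinction flag.
#' @return A tibble of class `mito_trajectory` with columns `time`, `s`,
#'   `c`; attributes `params` and `extinct`.
#' @examples
#' p <- kinetic_params()
#' traj <- simulate_density(p, init = c(s = 2, c = 1), times = seq(0, 200, 0.5))
#' tail(traj)
#' @export
simulate_density <- function(params, init = NULL, times = seq(0, 200, by = 0.5),
                             rtol = 1e-8, atol = 1e-10, extinction_tol = 1e-12) {
  params <- as_kinetic_params(params)
  check_time_grid(times)
  fp <- steady_state(params)
  if (is.null(init)) {
    if (is.null(fp$homeostatic)) abort("no homeostatic state; supply `init`")
    init <- fp$homeostatic
  }
  if (is.data.frame(init)) init <- unlist(init[1, c("s", "c")])
  init <- c(s = init[["s"]], c = init[["c"]])
  if (any(!is.finite(init)) || any(init < 0)) abort("init must be non-negative and finite")

  sol <- deSolve::ode(
    y = init, times = times, func = rhs_core, parms = params,
    method = "lsoda", rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    abort(paste("ODE solver failed; istate =", attr(sol, "istate")[1]))
  }
  out <- tibble::tibble(
    time = sol[, "time"],
    s = pmax(sol[, "s"], 0),
    c = pmax(sol[, "c"], 0)
  )
  s_ref <- if (is.null(fp$homeostatic)) 1 else fp$homeostatic[["s"]]
  extinct <- init[["s"]] == 0 || any(out$s < extinction_tol * s_ref)
  new_trajectory(out, params = params, extinct = extinct)
}

new_trajectory <- function(tbl, params, extinct = FALSE) {
  structure(tbl,
    class = c("mito_trajectory", class(tibble::tibble())),
    params = params, extinct = extinct
  )
}

check_time_grid <- function(times) {
  if (length(times) < 2 || any(!is.finite(times)) || any(diff(times) <= 0) ||
      times[1] < 0) {
    abort("`times` must be a non-negative, strictly increasing grid")
  }
  invisible(times)
}

#' Homeostatic density as a function of mitogen supply
#'
#' Evaluates the dose-response law of the model: above the critical supply
#' rate `mu_c = k*c0` the homeostatic density is exactly affine in the
#' supply rate, `s*(mu) = (mu - k*c0)/kprime` (slope `1/kprime`); at or
#' below `mu_c` the only stable state is the loss state and the density
#' is 0.  This is the model's account of the linear dependence of stem cell
#' density on mitogen gene dosage.
#'
#' @param params A [kinetic_params()] object (its `mu` is ignored).
#' @param mu Vector of supply rates (> 0), c0-units per day.
#' @return A tibble with columns `mu` and `s_star`.
#' @examples
#' dose_response(kinetic_params(), mu = c(0.15, 0.2, 0.25, 0.3))
#' @export
dose_response <- function(params, mu) {
  params <- as_kinetic_params(params)
  if (length(mu) == 0) abort("`mu` must be non-empty")
  if (any(!is.finite(mu)) || any(mu <= 0)) abort("supply rates must be positive")
  s_star <- pmax(0, (mu - params$k * params$c0) / params$kprime)
  tibble::tibble(mu = mu, s_star = s_star)
}
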