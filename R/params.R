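#' Rate constants of the mitogen-competition model
#'
#' Bundles the kinetic parameters of the mean-field consumer-resource model
#' in which a stem cell population of density `s` (cells/mm of tubule)
#' consumes a mitogen of concentration `c` that biases cell fate.  The
#' mitogen is supplied at constant rate `mu`, degrades at rate `k`, and is
#' consumed by stem cells at per-cell rate `kprime`; at the threshold
#' concentration `c0` duplication and differentiation-loss exactly balance.
#'
#' The net per-cell growth rate is linear in concentration,
#' `r(c) = lam * (c - c0) / c0`, and is split into a duplication rate
#' `alpha(c) = beta + r(c)/2` and a loss rate `ell(c) = beta - r(c)/2`
#' (each clipped at zero), so `beta` is the baseline turnover rate at
#' homeostasis.  Concentration is measured in units of `c0` throughout, so
#' `mu` is the quantity conventionally plotted as mu/c0 (per day).
#'
#' @param mu Mitogen supply rate, c0-units per day.
#' @param k Mitogen degradation rate, per day.
#' @param kprime Per-stem-cell consumption rate, mm cell^-1 day^-1.
#' @param c0 Threshold concentration (concentration units; default 1).
#' @param lam Fate-sensitivity rate lambda, per day: slope of the net
#'   growth rate in `c` at `c0`.
#' @param beta Baseline turnover rate, per day.  Must satisfy
#'   `beta >= lam/2` for non-negative event rates down to `c = 0`;
#'   violations are allowed with a warning (rates are clipped at 0).
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params()
#' steady_state(p)
#' @export
kinetic_params <- function(mu = 0.3, k = 0.1, kprime = 0.01, c0 = 1,
                           lam = 0.1, beta = 0.05) {
  vals <- c(mu = mu, k = k, kprime = kprime, c0 = c0, lam = lam, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all kinetic parameters must be finite and strictly positive")
  }
  if (beta < lam / 2) {
    warn(paste0(
      "beta (", beta, ") < lam/2 (", lam / 2,
      "): duplication/loss rates will be clipped at 0 near c = 0"
    ))
  }
  structure(as.list(vals), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf(
    "  mu = %g /d, k = %g /d, kprime = %g mm/cell/d, c0 = %g\n  lam = %g /d, beta = %g /d\n",
    x$mu, x$k, x$kprime, x$c0, x$lam, x$beta
  ))
  invisible(x)
}

#' @rdname kinetic_params
#' @param x Object to test or convert.
#' @export
is_kinetic_params <- function(x) inherits(x, "kinetic_params")

as_kinetic_params <- function(x) {
  if (is_kinetic_params(x)) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(do.call(kinetic_params, x[c("mu", "k", "kprime", "c0", "lam", "beta")]))
  }
  abort("cannot interpret object as kinetic_params")
}

#' Parameters of the two-compartment stem/progenitor model
#'
#' Extends [kinetic_params()] with a differentiation-destined progenitor
#' compartment `D` fed by the loss channel of the stem compartment `S`.
#' Both compartments draw on the same mitogen pool: progenitors consume at
#' per-cell rate `kprime_d` (default: same as stem cells, since the
#' reception machinery is shared across undifferentiated spermatogonia).
#' Progenitors exit to the committed compartment at rate `gamma`; rare
#' reversion D -> S (`omega`) and stem cell death (`delta`) are optional.
#'
#' @param base A [kinetic_params()] object.
#' @param kprime_d Per-progenitor consumption rate (>= 0), mm cell^-1 day^-1.
#' @param gamma Progenitor exit rate, per day (> 0).
#' @param omega Reversion rate D -> S, per day (>= 0).
#' @param delta Stem cell death rate, per day (>= 0).
#' @return An object of class `extended_params`.
#' @export
extended_params <- function(base = kinetic_params(), kprime_d = base$kprime,
                            gamma = 0.1, omega = 0, delta = 0) {
  base <- as_kinetic_params(base)
  if (!is.finite(kprime_d) || kprime_d < 0) abort("kprime_d must be >= 0")
  if (!is.finite(gamma) || gamma <= 0) abort("gamma must be > 0")
  if (!is.finite(omega) || omega < 0) abort("omega must be >= 0")
  if (!is.finite(delta) || delta < 0) abort("delta must be >= 0")
  structure(
    list(base = base, kprime_d = kprime_d, gamma = gamma,
         omega = omega, delta = delta),
    class = "extended_params"
  )
}

#' @export
print.extended_params <- function(x, ...) {
  cat("<extended_params>\n")
  print(x$base)
  cat(sprintf(
    "  kprime_d = %g mm/cell/d, gamma = %g /d, omega = %g /d, delta = %g /d\n",
    x$kprime_d, x$gamma, x$omega, x$delta
  ))
  invisible(x)
}
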