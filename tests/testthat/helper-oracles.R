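# shared fixtures and independent oracles

# default parameter set used throughout
p_default <- function() kinetic_params()

# oscillatory regime: complex-conjugate eigenvalues at the homeostatic point
p_oscillatory <- function() kinetic_params(lam = 0.2, beta = 0.1)

# closed-form Jacobian eigenvalues at the homeostatic point, derived by hand
# from the analytic partial derivatives (independent of the package's
# finite-difference route):
#   J = [ 0,            lam * s_star / c0 ]
#       [ -kprime,     -k - kprime * s_star / c0 ]
eigen_homeostatic_closed_form <- function(p) {
  s_star <- (p$mu - p$k * p$c0) / p$kprime
  tr <- -(p$k + p$kprime * s_star / p$c0)
  det <- p$lam * p$kprime * s_star / p$c0
  disc <- as.complex(tr^2 - 4 * det)
  c((tr + sqrt(disc)) / 2, (tr - sqrt(disc)) / 2)
}

# random parameter draw with a homeostatic state, bounded away from the
# critical supply so convergence times stay moderate
draw_params <- function() {
  k <- runif(1, 0.05, 0.3)
  c0 <- runif(1, 0.5, 2)
  mu <- k * c0 * runif(1, 1.5, 4)
  lam <- runif(1, 0.05, 0.4)
  kinetic_params(mu = mu, k = k, kprime = runif(1, 0.005, 0.05),
                 c0 = c0, lam = lam, beta = lam / 2 + runif(1, 0.01, 0.2))
}
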