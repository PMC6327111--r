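#' Configuration of the spatial agent-based simulation
#'
#' The tubule is a periodic 1D domain of length `L` discretized at spacing
#' `h` for the mitogen field, which diffuses (`D_c`), is produced by
#' localized sources, decays at rate `k` and is consumed by agents in the
#' containing grid cell.  Agents are motile (diffusivity `D_a`, symmetric
#' Gaussian steps — no chemotaxis) and duplicate or leave the pool by
#' Bernoulli thinning at rates set by the local concentration through the
#' same fate law as the mean-field model.
#'
#' Two strides are used: the field is advanced at `dt_field`, bounded by
#' the explicit-diffusion stability limit `h^2 / (2 D_c)`, while agent
#' motility/fate updates run every `dt_agent` (an integer multiple of
#' `dt_field`), bounded so that `rate * dt_agent <= 0.1` for thinning
#' accuracy.  Both default to the largest admissible values.
#'
#' @param L Domain length, mm (must be a multiple of `h`).
#' @param h Field grid spacing, mm.
#' @param D_c Mitogen diffusivity, mm^2/day.
#' @param D_a Agent motility diffusivity, mm^2/day.
#' @param T Total simulated time, days.
#' @param dt_field Field step, days; `NULL` = auto (stability limit x 0.9).
#' @param dt_agent Agent step, days; `NULL` = auto
#'   (`min(0.01, 0.1/max_rate)`, rounded down to a multiple of `dt_field`).
#' @param seed RNG seed applied at the start of [run_spatial()].
#' @return Object of class `spatial_config`.
#' @export
spatial_config <- function(L = 50, h = 0.05, D_c = 10, D_a = 0.01, T = 300,
                           dt_field = NULL, dt_agent = NULL, seed = 1) {
  if (abs(L / h - round(L / h)) > 1e-9) abort("`h` must divide `L`")
  if (any(c(L, h, D_c, D_a, T) <= 0)) abort("L, h, D_c, D_a, T must be positive")
  dt_stab <- h^2 / (2 * D_c)
  if (is.null(dt_field)) dt_field <- 0.9 * dt_stab
  if (dt_field > dt_stab + 1e-15) {
    abort(sprintf("dt_field = %g violates the diffusion stability limit %g", dt_field, dt_stab))
  }
  structure(
    list(L = L, h = h, D_c = D_c, D_a = D_a, T = T,
         dt_field = dt_field, dt_agent = dt_agent, seed = seed),
    class = "spatial_config"
  )
}

#' Mitogen source maps
#'
#' Sources are Gaussian bumps (rather than grid-sensitive point sources)
#' described by a tibble with columns `position` (mm), `width` (mm, the
#' Gaussian sd) and `rate` (c0-units x mm / day, the integrated production
#' of the source).  `uniform_sources()` builds the spatially homogeneous
#' limit in which the ABM reduces to the mean-field model: total supply
#' `mu * L` spread evenly, so the local production density is `mu`.
#'
#' @param position,width,rate Source parameters (vectors, recycled).
#' @return A `source_map` tibble.
#' @export
source_map <- function(position, width = 0.25, rate) {
  tbl <- tibble::tibble(position = position, width = width, rate = rate)
  if (any(tbl$rate < 0) || any(tbl$width <= 0)) abort("rates must be >= 0 and widths > 0")
  structure(tbl, class = c("source_map", class(tbl)))
}

#' @rdname source_map
#' @param L Domain length, mm.
#' @param mu Supply rate density, c0-units per day (as in the mean-field
#'   model); the total supply is `mu * L`.
#' @export
uniform_sources <- function(L, mu) {
  structure(
    tibble::tibble(position = NA_real_, width = Inf, rate = mu * L),
    class = c("source_map", class(tibble::tibble()))
  )
}

# discretized production density (c0-units/day per grid cell), normalized
# so that sum(prod) * h equals the map's total rate to within 1e-12
discretize_sources <- function(sources, L, h) {
  m <- round(L / h)
  x <- (seq_len(m) - 0.5) * h
  prod <- numeric(m)
  for (i in seq_len(nrow(sources))) {
    r <- sources$rate[i]
    if (r == 0) next
    if (!is.finite(sources$width[i])) {       # uniform source
      prod <- prod + r / L
      next
    }
    d <- periodic_distance(x, sources$position[i], L)
    w <- exp(-d^2 / (2 * sources$width[i]^2))
    w <- w / (sum(w) * h)                      # exact discrete normalization
    prod <- prod + r * w
  }
  prod
}

periodic_distance <- function(x, x0, L) {
  d <- abs(x - x0) %% L
  pmin(d, L - d)
}

#' Add a time-limited bead source
#'
#' Models the implantation of a mitogen-soaked bead next to the tubule: an
#' additional localized source of strength `extra_rate` switched on for
#' `duration` days from `start`.  With `extra_rate = 0` the schedule is the
#' vehicle (BSA) control: run under the same seed it reproduces the control
#' simulation exactly, so bead effects can be read off paired runs with
#' common random numbers.
#'
#' @param sources A `source_map`.
#' @param position Bead position, mm.
#' @param extra_rate Additional integrated production, c0-units x mm / day
#'   (>= 0).
#' @param duration Days the bead remains active (> 0).
#' @param start Activation time, days.
#' @param width Bump width of the bead source, mm.
#' @return The `source_map` with a `bead` attribute read by [run_spatial()].
#' @export
add_bead <- function(sources, position, extra_rate, duration, start = 0,
                     width = 0.25) {
  if (extra_rate < 0) abort("`extra_rate` must be >= 0")
  if (duration <= 0) abort("`duration` must be positive")
  attr(sources, "bead") <- list(position = position, rate = extra_rate,
                                start = start, duration = duration,
                                width = width)
  sources
}

#' Run the spatial agent-based simulation
#'
#' @param config A [spatial_config()].
#' @param params A [kinetic_params()]; `mu` is ignored (supply comes from
#'   `sources`), the fate law uses `lam`, `beta`, `c0` and consumption uses
#'   `kprime`, decay `k`.
#' @param sources A [source_map()], possibly carrying a bead schedule from
#'   [add_bead()].
#' @param init_density Initial agent density, cells/mm (agents placed
#'   uniformly at random); alternatively `init_positions` overrides.
#' @param init_positions Optional explicit initial positions, mm.
#' @param init_field Initial concentration (scalar or per-cell); default
#'   `c0`.
#' @param record_dt Days between population records.
#' @param checkpoint_times Times (days) at which agent positions are
#'   snapshotted; default: every 5 days over the second half of the run.
#' @return Object of class `spatial_result`: `population` tibble
#'   (`time`, `n`, `density`, `mean_c`), `checkpoints` tibble
#'   (`time`, `position`), `final_field` tibble (`x`, `concentration`),
#'   `final_positions`, event counters, `mass_balance_err`, `extinct`
#'   flag, plus the config/params/sources used.
#' @export
run_spatial <- function(config, params, sources, init_density = NULL,
                        init_positions = NULL, init_field = NULL,
                        record_dt = 0.5, checkpoint_times = NULL) {
  stopifnot(inherits(config, "spatial_config"))
  params <- as_kinetic_params(params)
  L <- config$L; h <- config$h
  m <- round(L / h)

  # strides: field at the stability limit, agents capped by thinning accuracy
  max_rate <- max(duplication_rate(c(0, 5 * params$c0), params),
                  loss_rate(c(0, 5 * params$c0), params))
  dt_field <- config$dt_field
  dt_agent <- config$dt_agent
  if (is.null(dt_agent)) dt_agent <- min(0.01, 0.1 / max_rate)
  n_sub <- max(1L, floor(dt_agent / dt_field))
  dt_agent <- n_sub * dt_field
  if (dt_agent * max_rate > 0.1 + 1e-12) {
    abort("cannot satisfy rate * dt_agent <= 0.1; decrease dt_agent")
  }
  n_steps <- ceiling(config$T / dt_agent)

  production <- discretize_sources(sources, L, h)
  bead <- attr(sources, "bead")
  if (is.null(bead)) {
    bead_prod <- numeric(m); bead_on <- Inf; bead_off <- Inf
  } else {
    bead_prod <- discretize_sources(
      source_map(bead$position, bead$width, bead$rate), L, h
    )
    bead_on <- bead$start; bead_off <- bead$start + bead$duration
  }

  if (is.null(init_field)) init_field <- params$c0
  field0 <- rep_len(init_field, m)

  withr::local_seed(config$seed)
  if (is.null(init_positions)) {
    if (is.null(init_density)) abort("supply `init_density` or `init_positions`")
    n0 <- rpois(1, init_density * L)
    init_positions <- runif(n0, 0, L)
  }
  if (any(init_positions < 0 | init_positions >= L)) {
    abort("initial positions must lie in [0, L)")
  }

  record_every <- max(1L, round(record_dt / dt_agent))
  if (is.null(checkpoint_times)) {
    checkpoint_times <- seq(config$T / 2, config$T, by = 5)
  }
  cp_steps <- sort(unique(pmin(pmax(round(checkpoint_times / dt_agent), 1L), n_steps)))

  res <- abm_run_cpp(
    field0, init_positions, production, bead_prod, bead_on, bead_off,
    L, h, config$D_c, config$D_a, dt_field, n_sub, n_steps,
    params$k, params$kprime, params$c0, params$lam, params$beta,
    record_every, as.integer(cp_steps)
  )

  cps <- purrr::map2_dfr(cp_steps, res$checkpoints, function(st, p) {
    tibble::tibble(time = st * dt_agent, position = as.numeric(p))
  })
  structure(
    list(
      population = tibble::tibble(
        time = res$time, n = res$n, density = res$n / L, mean_c = res$mean_c
      ),
      checkpoints = cps,
      final_field = tibble::tibble(
        x = (seq_len(m) - 0.5) * h, concentration = res$final_field
      ),
      final_positions = as.numeric(res$final_positions),
      births = res$births, deaths = res$deaths,
      clip_events = res$clip_events,
      mass_balance_err = res$mass_err_max,
      extinct = res$extinct,
      t_end = res$t_end,
      dt_field = dt_field, dt_agent = dt_agent,
      config = config, params = params, sources = sources
    ),
    class = "spatial_result"
  )
}

#' @export
print.spatial_result <- function(x, ...) {
  cat("<spatial_result>\n")
  cat(sprintf("  L = %g mm, T = %g d (reached %g d)%s\n", x$config$L,
              x$config$T, x$t_end, if (x$extinct) " [EXTINCT]" else ""))
  n_end <- if (nrow(x$population)) tail(x$population$n, 1) else length(x$final_positions)
  cat(sprintf("  final agents: %d (%.2f cells/mm); births %d, losses %d\n",
              length(x$final_positions), length(x$final_positions) / x$config$L,
              as.integer(x$births), as.integer(x$deaths)))
  cat(sprintf("  field mass-balance max rel err: %.2e; clip events: %d\n",
              x$mass_balance_err, as.integer(x$clip_events)))
  invisible(x)
}

#' Count agents in 1-mm bins along the tubule
#'
#' Half-open bins `[i*w, (i+1)*w)`; counts sum to the number of positions.
#'
#' @param positions Positions in `[0, L)`, mm.
#' @param L Domain length, mm (multiple of `bin_width`).
#' @param bin_width Bin width, mm (default 1, the unit used for the
#'   clustering statistics).
#' @return Tibble of class `binned_counts` with `bin_start_mm`, `count`.
#' @export
bin_counts <- function(positions, L, bin_width = 1) {
  if (abs(L / bin_width - round(L / bin_width)) > 1e-9) {
    abort("`bin_width` must divide `L`")
  }
  if (length(positions) && any(positions < 0 | positions >= L)) {
    abort("positions must lie in [0, L)")
  }
  nb <- round(L / bin_width)
  idx <- floor(positions / bin_width) + 1
  cnt <- tabulate(idx, nbins = nb)
  structure(
    tibble::tibble(bin_start_mm = (seq_len(nb) - 1) * bin_width, count = cnt),
    class = c("binned_counts", class(tibble::tibble())),
    bin_width = bin_width
  )
}

#' Mean agent density versus distance to the nearest source
#'
#' Pools all checkpoint snapshots, assigns each agent the periodic distance
#' to its nearest source, and normalizes the per-distance-bin counts by the
#' exposure (tubule length at that distance x number of snapshots), giving
#' densities in cells/mm comparable across bins.
#'
#' @param result A `spatial_result` with checkpoint positions.
#' @param sources A `source_map` with finite positions.
#' @param bin_width Distance bin width, mm.
#' @return Tibble with `distance`, `count`, `exposure_mm`, `density`.
#' @export
density_vs_distance <- function(result, sources, bin_width = 0.5) {
  if (nrow(result$checkpoints) == 0) abort("result has no checkpoint positions")
  spos <- sources$position[is.finite(sources$position)]
  if (length(spos) == 0) abort("sources have no localized positions")
  L <- result$config$L
  n_snap <- length(unique(result$checkpoints$time))
  dist_to_src <- function(x) {
    do.call(pmin, lapply(spos, function(s) periodic_distance(x, s, L)))
  }
  d_agents <- dist_to_src(result$checkpoints$position)
  # exposure from a fine partition of the domain
  xg <- seq(0, L - L / 20000, length.out = 20000) + L / 40000
  d_dom <- dist_to_src(xg)
  edges <- seq(0, max(d_dom) + bin_width, by = bin_width)
  cut_idx <- function(d) pmin(findInterval(d, edges), length(edges) - 1)
  cnt <- tabulate(cut_idx(d_agents), nbins = length(edges) - 1)
  expo <- tabulate(cut_idx(d_dom), nbins = length(edges) - 1) * (L / 20000)
  keep <- expo > 0
  tibble::tibble(
    distance = edges[-length(edges)][keep] + bin_width / 2,
    count = cnt[keep],
    exposure_mm = expo[keep] * n_snap,
    density = cnt[keep] / (expo[keep] * n_snap)
  )
}
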