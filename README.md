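# mitocomp

Simulation and inference tools for **mitogen competition**, a
consumer–resource mechanism of stem cell density homeostasis in open
niches.  The motivating system is the GFRα1+ spermatogonial population of
the mouse seminiferous tubule: motile stem cells consume a fate-biasing
mitogen (FGF) that somatic cells supply at a steady rate, so cell density
and signal concentration regulate each other by negative feedback — no
anatomical niche, no counting mechanism, just supply and demand.

The package is for quantitative stem cell biologists and modelers who
want to simulate this feedback, fit it to depletion–recovery data, and
score the spatial statistics it predicts.

## The model

Stem cell density $s$ (cells/mm) and mitogen concentration $c$ (units of
the balance threshold $c_0$) obey

$$\frac{ds}{dt} = \lambda\,\frac{c - c_0}{c_0}\,s,
\qquad
\frac{dc}{dt} = \mu - k\,c - k'\,s\,\frac{c}{c_0},$$

where $\mu$ is the supply rate, $k$ the degradation rate and $k'$ the
per-cell consumption rate.  Above the critical supply $\mu_c = k c_0$ the
system has a stable homeostatic state

$$s^* = \frac{\mu - k c_0}{k'}, \qquad c^* = c_0,$$

so the homeostatic density is **linear in the supply rate** (the
gene-dosage law) while the concentration — and hence per-cell fate
behavior — is **pinned at the threshold** regardless of supply.  After an
abrupt depletion the feedback produces an **overshoot** and decaying
oscillations whenever the Jacobian eigenvalues are complex.  The package
implements this mean-field core plus a two-compartment stem/progenitor
extension, a stochastic agent-based model on a periodic 1D tubule with
localized sources, recovery fitting with mutant prediction, and the
clustering/preference statistics used to quantify spatial bias.

## Worked example

```r
library(mitocomp)

p <- kinetic_params(mu = 0.3, k = 0.1, kprime = 0.01, c0 = 1,
                    lam = 0.2, beta = 0.1)
steady_state(p)
#> <mito_fixed_points>
#>   critical supply mu_c = 0.1 /d (mu = 0.3)
#>   homeostatic state: s* = 20 cells/mm, c* = 1 (stable, oscillatory, omega = 0.1323 rad/d)
#>   loss state: s = 0, c = 3 (unstable)
```

The homeostatic density is 20 cells/mm at concentration exactly $c_0$;
the complex eigenvalue pair (damped angular frequency 0.1323 rad/day,
i.e. a ~47.5-day period) says recovery from injury will oscillate.
Deplete 90% of the pool, let it recover, and fit the model back to the
sampled series:

```r
fp  <- steady_state(p)
tr  <- simulate_density(p, init = deplete(fp$homeostatic, 0.9),
                        times = seq(0, 300, 0.25))
detect_oscillation(tr, s_star = 20)
#> # A tibble: 1 × 6
#>   overshoot first_peak_time first_peak_rel_amplitude period_days n_extrema
#> * <lgl>               <dbl>                    <dbl>       <dbl>     <int>
#> 1 TRUE                 24.5                    0.110        47.8         3
#> # i 1 more variable: period_defined <lgl>

ser <- gen_recovery_series(p, depletion_fraction = 0.9, noise_cv = 0, seed = 1)
fit <- fit_recovery(ser, n_starts = 16, seed = 1)
fit
#> <mito_fit>
#>   lam = 0.2 /d, k = 0.1 /d, kappa = 0.2 /d
#>   x0 = s(0)/s* = 0.1, y0 = c(0)/c0 = 1
#>   RSS = 3.404e-17 over 10 points; converged: TRUE
```

The density overshoots the set point by 11% at day 24.5 and the
peak-to-peak period (47.8 d) matches the linearized prediction
$2\pi/\omega$.  The fit recovers the generating nondimensional rates
($\lambda$, $k$, $\kappa = k' s^*/c_0$) exactly from the noiseless
series.  `predict_mutant(fit, supply_scale)` then re-simulates the fit at
scaled mitogen supply, e.g. for a dosage mutant.  The dose–response law
itself:

```r
dose_response(p, mu = c(0.15, 0.2, 0.25, 0.3))
#> # A tibble: 4 × 2
#>      mu s_star
#>   <dbl>  <dbl>
#> 1  0.15      5
#> 2  0.2      10
#> 3  0.25     15
#> 4  0.3      20
```

Spatial statistics on clustered per-1-mm counts:

```r
counts <- gen_clustered_counts(10000, mean = 8, vmr = 3, seed = 1)
variance_to_mean(counts)
#> [1] 2.997531
poisson_gof(gen_clustered_counts(105, mean = 8, vmr = 3, seed = 1))$p_value
#> [1] 1.214396e-05
```

A variance-to-mean ratio of ~3 (Poisson would be 1) and a ~10⁻⁵
rejection of spatial randomness already at the 105-bin scale — the clustered
arrangement the agent-based model produces around localized sources.  See
`vignettes/mitogen-competition.Rmd` for the full methods account and
`run_pipeline()` for the one-call synthetic pipeline.

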