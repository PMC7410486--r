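# glvnoise

Stochastic generalized Lotka-Volterra (gLV) simulation and the complete
noise characterization toolkit for microbial community time series.

Microbial abundance series — gut microbiome, plankton, skin — share a
striking stochastic anatomy: heavy-tailed rank abundance profiles that stay
stable over time, white-to-pink noise color independent of a species' mean
abundance, successive-day jumps that scale almost linearly with abundance,
abundance ratios with lognormal widths of order one, and neutrality tests
that come out on the *niche* side.  `glvnoise` lets you ask which dynamical
models reproduce that anatomy.  Its central result, reproducible end to
end on synthetic communities, is that a **stochastic logistic model** —
the gLV system

$$\dot x_i = g_i x_i + \omega_{ii} x_i^2 + (\text{noise}),$$

with *no interspecies interactions*, large **linear multiplicative noise**
($\sigma_i x_i\, dW$), and self-interactions $\omega_{ii}$ spanning several
orders of magnitude — reproduces every one of those properties, including
the niche verdicts of neutrality tests.

## What's inside

* **Model building** — `glv_params()`, `sample_interactions()` (random
  ensemble with off-diagonals $N(0,\alpha^2)$), `impose_growth()`
  ($\hat g = -\omega x^*$ pins any desired steady state),
  `solve_steady_state()`, `linear_stability()`.
* **SDE simulation** — `simulate_glv()`: Euler-Maruyama with three noise
  channels per species (linear, square-root/demographic with a
  sub-unity-abundance guard, additive), non-negativity by clipping,
  bit-reproducible under a seed (`noise_spec()`, Rcpp core).
* **Characterization** — `power_spectrum()`, `psd_slope()`,
  `classify_color()`, `noise_color()`; `successive_differences()` and
  `difference_scaling()`; `ratio_widths()` (mean-one lognormal MLE +
  Kolmogorov-Smirnov); `rank_abundance()`; `to_relative()`.
* **Neutrality** — `gaussian_summary()`, `neutral_projection()`,
  `kl_gaussian()`, `kl_neutrality()` (closed-form multivariate Gaussian
  Kullback-Leibler divergence to the exchangeable community) and
  `neutral_covariance_test()` (grouping-invariance test against a
  matched Wright-Fisher null; `wright_fisher_series()`).
* **Synthetic experiments** — `community_blueprint()` /
  `generate_community()` (heavy-tailed stool-like communities),
  `calibrate_color_curve()` + `infer_self_interactions()` (noise color
  → self-interaction inversion), `scan_noise_mix()`, `scan_ratio_width()`,
  `run_community_study()`.
* **I/O and CLI** — TSV series round-tripping
  (`read_abundance_series()` / `write_abundance_series()`) and a thin
  command-line wrapper (`inst/scripts/glvnoise`) with `simulate`,
  `characterize` and `neutrality` subcommands.

Everything is tibble-first and pipe-friendly; result objects have
`tidy()` / `glance()` methods and `autoplot()` / `plot_*()` graphics.

## A worked example

```r
library(glvnoise)

bp <- community_blueprint(S = 40, n_steps = 500)  # stool-like defaults
series <- simulate_community(bp, seed = 1)

glance(difference_scaling(series))
#> # A tibble: 1 × 4
#>   slope intercept r_squared n_species
#>   <dbl>     <dbl>     <dbl>     <int>
#> 1 0.977    -0.196     0.987        40

head(noise_color(series), 4)
#> # A tibble: 4 × 4
#>   species mean_abundance  slope color
#>   <chr>            <dbl>  <dbl> <chr>
#> 1 sp01              6.25 -0.328 white
#> 2 sp02            163.    0.115 white
#> 3 sp03              2.32 -0.409 white
#> 4 sp04           5295.   -0.687 pink

neutrality_measures(series, n_partitions = 60, n_null = 100, seed = 2)
#> # A tibble: 1 × 3
#>   kl_divergence   nct_p nct_label
#>           <dbl>   <dbl> <chr>
#> 1          203. 0.00990 niche
```

Read it off: the jump-size slope of 0.98 is the fingerprint of linear
(environmental) noise; the per-species spectral slopes sit in the
white-pink band regardless of four decades of abundance differences; the
ratio widths are of order one (`median(ratio_widths(series)$sigma_hat)`
≈ 1.0); and although the 40 species do not interact at all, the neutral
covariance test rejects neutrality (p ≈ 0.01) — heterogeneous fluctuation
scales alone break the grouping invariance that neutral drift predicts.
The methods vignette
(`vignettes/stochastic-logistic-noise.Rmd`) explains each estimator, the
calibration of the defaults, and the design decisions.

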