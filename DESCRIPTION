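Package: glvnoise
Title: Stochastic Lotka-Volterra Simulation and Noise Characterization of
    Microbial Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates generalized Lotka-Volterra and stochastic logistic
    community dynamics under linear multiplicative, square-root (demographic)
    and additive noise via Euler-Maruyama integration, and characterizes
    abundance time series the way microbial ecologists do: noise color from
    the slope of the power spectral density, scaling of successive-difference
    magnitudes with mean abundance, lognormal widths of successive abundance
    ratios, rank abundance profiles, and two neutrality measures (a Gaussian
    Kullback-Leibler divergence to an exchangeable community and a neutral
    covariance test against a Wright-Fisher null). Includes heavy-tailed
    synthetic community generators, a noise-color calibration curve for
    inferring self-interaction strengths from mean abundance and color, and
    tidy orchestration of parameter scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
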