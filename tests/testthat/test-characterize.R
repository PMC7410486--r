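test_that("periodogram satisfies Parseval and basic scaling", {
  set.seed(1)
  x <- rnorm(512)
  ps <- power_spectrum(x)
  expect_true(all(ps$power >= 0))
  expect_equal(max(ps$frequency), floor(512 / 2) / 512)
  # Parseval: total power over all Fourier frequencies matches the variance
  expect_equal(2 * sum(ps$power) / 512, var(x) * (512 - 1) / 512,
               tolerance = 0.01)
  # multiplying by a constant scales power by c^2, slope unchanged
  ps3 <- power_spectrum(3 * x)
  expect_equal(ps3$power, 9 * ps$power)
  expect_equal(psd_slope(ps3$frequency, ps3$power),
               psd_slope(ps$frequency, ps$power))
  expect_error(power_spectrum(rnorm(32)), "short")
  expect_error(power_spectrum(rep(1, 100)), "degenerate")
})

test_that("spectral slope recovers generating exponents", {
  # an exact power law injected into the fit comes back to precision
  f <- 10^seq(-3, -0.3, length.out = 200)
  for (gamma in c(0, -1, -2.5)) {
    expect_equal(psd_slope(f, f^gamma), gamma, tolerance = 1e-10)
  }

  # white noise: slope near 0, averaged over replicates
  set.seed(2)
  sl_white <- replicate(20, {
    ps <- power_spectrum(rnorm(512))
    psd_slope(ps$frequency, ps$power)
  })
  expect_lt(abs(mean(sl_white)), 0.2)

  # random walk: Brownian 1/f^2 spectrum
  set.seed(3)
  sl_brown <- replicate(20, {
    ps <- power_spectrum(cumsum(rnorm(512)))
    psd_slope(ps$frequency, ps$power)
  })
  expect_lt(abs(mean(sl_brown) + 2), 0.3)
})

test_that("spline estimator reads darker on low-frequency-bending spectra", {
  # sampled-OU theory spectrum bends flat at low frequencies; taking the
  # minimum derivative of a spline must give a slope at least as dark as
  # the linear fit over the retained band
  phi <- exp(-10^-0.5)
  k <- seq_len(500); f <- k / 1000
  power <- (1 - phi^2) / (1 - 2 * phi * cos(2 * pi * f) + phi^2)
  lin <- psd_slope(f, power, method = "linear")
  spl <- psd_slope(f, power, method = "spline")
  expect_lte(spl, lin)
})

test_that("noise colors classify by nearest anchor", {
  expect_identical(classify_color(c(0, -1, -2, -3)),
                   c("white", "pink", "brown", "black"))
  expect_identical(classify_color(c(-1.4, 0.3, -5)),
                   c("pink", "white", "black"))
  bp <- test_blueprint(S = 6, n_steps = 200)
  nc <- noise_color(simulate_community(bp, seed = 1))
  expect_identical(nc$color, classify_color(nc$slope))
})

test_that("successive differences scale with the species and flag degeneracy", {
  # exact copies scaled by c land on a unit slope line through their points
  set.seed(4)
  x <- abs(cumsum(rnorm(200))) + 5
  m <- cbind(x, 10 * x, 100 * x)
  d <- successive_differences(series_from_matrix(m))
  expect_equal(unname(d$mean_abs_diff[2] / d$mean_abs_diff[1]), 10)
  fit <- difference_scaling(series_from_matrix(m))
  expect_equal(fit$slope, 1, tolerance = 1e-10)

  expect_error(suppressWarnings(
    difference_scaling(series_from_matrix(matrix(1, 10, 3)))),
    "fluctuations")
  expect_warning(
    difference_scaling(series_from_matrix(cbind(m, 0))),
    "excluded"
  )
  expect_named(glance(fit), c("slope", "intercept", "r_squared", "n_species"))
})

test_that("ratio widths recover a known lognormal and flag degeneracy", {
  # self-consistency: ratios drawn from the fitted family itself come back
  # with the generating width and a good KS fit, under either centring
  set.seed(5)
  sigma_true <- 0.5
  for (ctr in c("median", "mean")) {
    ml <- if (ctr == "median") 0 else -sigma_true^2 / 2
    reps <- replicate(40, {
      r <- rlnorm(400, meanlog = ml, sdlog = sigma_true)
      x <- cumprod(c(100, r))
      rw <- ratio_widths(series_from_matrix(cbind(x, x, x)), center = ctr)
      c(rw$sigma_hat[1], rw$ks_p[1])
    })
    se <- sigma_true / sqrt(2 * 400)
    expect_lt(abs(mean(reps[1, ]) - sigma_true), 3 * se)
    expect_gt(mean(reps[2, ] > 0.05), 0.9)
  }

  rw0 <- ratio_widths(series_from_matrix(matrix(2, 100, 2)))
  expect_true(all(rw0$degenerate))
  expect_equal(rw0$sigma_hat, c(0, 0))

  # too few ratios gives NA fits, not an error
  rw_short <- ratio_widths(series_from_matrix(matrix(runif(20), 10, 2)))
  expect_true(all(is.na(rw_short$sigma_hat)))
})

test_that("rank abundance sorts, is permutation invariant, and matches its generator", {
  s <- series_from_matrix(matrix(c(3, 1, 2), 2, 3, byrow = TRUE))
  expect_equal(rank_abundance(s)$mean_abundance, c(3, 2, 1))

  set.seed(6)
  m <- matrix(rlnorm(50 * 40, 2, 1), 40, 50)
  prof1 <- rank_abundance(series_from_matrix(m))
  prof2 <- rank_abundance(series_from_matrix(m[, sample(50)]))
  expect_equal(prof1$mean_abundance, prof2$mean_abundance)

  # lognormal steady states: the sorted profile refits the generating
  # log-sd (sd of log10 abundances) within sampling tolerance
  bp <- test_blueprint(S = 80, n_steps = 100, sigma_lin = 0.1)
  prof <- rank_abundance(simulate_community(bp, seed = 7))
  sd_hat <- sd(log10(prof$mean_abundance))
  se <- 1.5 / sqrt(2 * 80)
  expect_lt(abs(sd_hat - 1.5), 4 * se)
})
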