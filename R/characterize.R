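#' Periodogram of a single trajectory
#'
#' Mean-removed standard periodogram at the positive Fourier frequencies:
#' \eqn{P(f_k) = |\mathrm{FFT}(x - \bar x)_k|^2 / n} at \eqn{f_k = k/(n
#' \delta t)}, \eqn{k = 1, \dots, \lfloor n/2 \rfloor}.  No taper or window is
#' applied; the low-frequency band distorted by windowing is instead dropped
#' at the fitting stage ([psd_slope()]).
#'
#' @param x numeric trajectory (>= 64 uniformly spaced points, no missing
#'   values).
#' @param delta_t sampling interval.
#' @return A tibble with columns `frequency` (1/time) and `power`.
#' @export
power_spectrum <- function(x, delta_t = 1) {
  n <- length(x)
  if (n < 64) stop("trajectory too short for spectral estimation (need >= 64 points)")
  if (anyNA(x)) stop("missing values in trajectory")
  if (var(x) == 0) stop("constant trajectory has a degenerate spectrum")
  z <- fft(x - mean(x))
  k <- seq_len(floor(n / 2))
  tibble::tibble(frequency = k / (n * delta_t),
                 power = Mod(z[k + 1])^2 / n)
}

#' Fitted log-log slope of a power spectrum
#'
#' The noise color of a time series is the slope of its power spectral
#' density on log-log axes.  Following standard practice for short ecological
#' series, the lowest decade of frequencies (below `10^cutoff_decades` times
#' the smallest positive frequency) is omitted before the least-squares fit,
#' because the windowing effect bends the spectrum there.
#'
#' The `"spline"` method is an alternative estimator: a smoothing spline is
#' fitted through the full log-log spectrum and the minimum of its derivative
#' is reported.  Because it takes the steepest local slope, it yields darker
#' (more negative) values when the spectrum bends at low frequencies; it is
#' provided for comparison and considered experimental.
#'
#' @param frequency,power periodogram vectors as from [power_spectrum()].
#' @param cutoff_decades how many decades of the lowest frequencies to drop
#'   (default 1).
#' @param method `"linear"` (default) or `"spline"`.
#' @return The fitted slope (a single number).
#' @export
psd_slope <- function(frequency, power, cutoff_decades = 1,
                      method = c("linear", "spline")) {
  method <- match.arg(method)
  keep <- power > 0 & frequency > 0
  frequency <- frequency[keep]; power <- power[keep]
  lf <- log10(frequency); lp <- log10(power)
  if (method == "spline") {
    if (length(lf) < 10) stop("too few frequencies for the spline fit")
    fit <- smooth.spline(lf, lp, df = min(8, length(lf) - 2))
    grid <- seq(min(lf), max(lf), length.out = 200)
    return(min(predict(fit, grid, deriv = 1)$y))
  }
  cut <- frequency >= 10^cutoff_decades * min(frequency)
  if (sum(cut) < 10) stop("fewer than 10 frequencies remain after the low-frequency cutoff")
  unname(coef(lm(lp[cut] ~ lf[cut]))[2])
}

#' Classify a spectral slope as a noise color
#'
#' White, pink, brown and black noise correspond to power-spectral-density
#' slopes around 0, -1, -2 and -3.  Classification is to the nearest anchor
#' (bin edges at -0.5, -1.5, -2.5); slopes above 0 are white and below -3
#' black.  The slope itself is the primitive quantity; the label is for
#' display.
#'
#' @param slope numeric vector of fitted slopes.
#' @return Character vector among `"white"`, `"pink"`, `"brown"`, `"black"`.
#' @export
classify_color <- function(slope) {
  stopifnot(all(is.finite(slope)))
  as.character(cut(slope, breaks = c(-Inf, -2.5, -1.5, -0.5, Inf),
                   labels = c("black", "brown", "pink", "white")))
}

#' Per-species noise color of a community series
#'
#' @param series an `abundance_series`.
#' @inheritParams psd_slope
#' @return A tibble with one row per species: `species`, `mean_abundance`,
#'   `slope`, `color`.  Species with constant trajectories are dropped with a
#'   warning.
#' @export
noise_color <- function(series, cutoff_decades = 1,
                        method = c("linear", "spline")) {
  method <- match.arg(method)
  mat <- series_matrix(series)
  dt <- sampling_interval(series)
  ok <- apply(mat, 2, var) > 0
  if (!all(ok)) {
    warning(sum(!ok), " constant species dropped from noise-color estimation")
  }
  purrr::map_dfr(colnames(mat)[ok], function(sp) {
    ps <- power_spectrum(mat[, sp], dt)
    sl <- psd_slope(ps$frequency, ps$power, cutoff_decades, method)
    tibble::tibble(species = sp, mean_abundance = mean(mat[, sp]),
                   slope = sl, color = classify_color(sl))
  })
}

#' Mean absolute successive differences per species
#'
#' Computes \eqn{\langle |x(t+\delta t) - x(t)| \rangle} and
#' \eqn{\langle x(t) \rangle} for every species: the typical jump size from
#' one sampling time to the next versus the species' mean abundance.
#'
#' @param series an `abundance_series` with >= 2 time points.
#' @return A tibble: `species`, `mean_abundance`, `mean_abs_diff`.
#' @export
successive_differences <- function(series) {
  mat <- series_matrix(series)
  if (nrow(mat) < 2) stop("need at least two time points")
  tibble::tibble(
    species = colnames(mat),
    mean_abundance = colMeans(mat),
    mean_abs_diff = colMeans(abs(diff(mat)))
  )
}

#' Scaling of jump size with mean abundance
#'
#' Regresses `log10(mean_abs_diff)` on `log10(mean_abundance)` across species
#' (ordinary least squares, equal weights).  The fitted slope diagnoses the
#' dominant noise channel: linear multiplicative noise gives slope 1,
#' square-root (demographic) noise about 0.66, additive noise 0; mixtures
#' interpolate.  Experimental microbial series sit near 1, the signature of
#' environmental (linear) noise.
#'
#' @param series an `abundance_series` with >= 3 species.
#' @return An object of class `diff_scaling`; see [tidy()] / [glance()]
#'   methods.  Species with zero mean abundance or zero mean difference are
#'   excluded (with a warning).
#' @export
difference_scaling <- function(series) {
  stats <- successive_differences(series)
  use <- stats$mean_abundance > 0 & stats$mean_abs_diff > 0
  if (any(!use)) {
    warning(sum(!use), " species without fluctuations excluded from the fit")
  }
  if (sum(use) < 3) stop("need >= 3 species with fluctuations for the regression")
  d <- stats[use, ]
  fit <- lm(log10(mean_abs_diff) ~ log10(mean_abundance), data = d)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n_species = nrow(d), data = stats),
    class = "diff_scaling"
  )
}

#' @export
print.diff_scaling <- function(x, ...) {
  cat("<diff_scaling> slope ", signif(x$slope, 3), " (R^2 ",
      signif(x$r_squared, 3), ", ", x$n_species, " species)\n", sep = "")
  invisible(x)
}

#' @rdname difference_scaling
#' @param x a `diff_scaling` object.
#' @param ... unused.
#' @export
tidy.diff_scaling <- function(x, ...) x$data

#' @rdname difference_scaling
#' @export
glance.diff_scaling <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_species = x$n_species)
}

# single-parameter MLE of the log-ratio width for a lognormal centred at one
# "median": log r ~ N(0, s^2)        -> s^2 = mean(log r^2)
# "mean":   log r ~ N(-s^2/2, s^2)   -> closed form from d/d(s^2) of the
#           likelihood: s^2 = 2 (sqrt(1 + mean(log r^2)) - 1)
lognormal_width_mle <- function(log_ratios, center = "median") {
  m2 <- mean(log_ratios^2)
  if (center == "median") sqrt(m2) else sqrt(2 * (sqrt(1 + m2) - 1))
}

#' Width of the distribution of successive abundance ratios
#'
#' For each species the ratios \eqn{r_t = x(t+\delta t)/x(t)} are fitted with
#' a one-parameter lognormal centred at one, since fluctuations around a
#' steady state have no net drift.  Two centring conventions are supported:
#' * `center = "median"` (default): \eqn{\log r \sim N(0, \hat\sigma^2)}.
#'   Successive ratios of a stationary reversible process have exactly
#'   symmetric log-ratios (the pair \eqn{(x_t, x_{t+\delta t})} is
#'   exchangeable), so this is the centring such data actually obey, and
#'   the one under which strong-noise simulations pass the goodness-of-fit
#'   test.
#' * `center = "mean"`: the lognormal's arithmetic mean is one,
#'   \eqn{\log r \sim N(-\hat\sigma^2/2, \hat\sigma^2)}.  At widths of
#'   order one this miscentres the fit of symmetric data by
#'   \eqn{\hat\sigma^2/2} and the Kolmogorov-Smirnov test detects it.
#'
#' The width \eqn{\hat\sigma} is the maximum-likelihood estimate; goodness
#' of fit is the p-value of a Kolmogorov-Smirnov test of the ratios against
#' the fitted lognormal.  The width measures fluctuation magnitude on a
#' scale independent of abundance; experimental series have widths of
#' order one.
#'
#' @param series an `abundance_series`.
#' @param min_ratios minimum number of valid (positive-abundance) ratios per
#'   species (default 50); species below it are flagged and get `NA` fits.
#' @param center `"median"` (default) or `"mean"`; see Details.
#' @return A tibble: `species`, `mean_abundance`, `sigma_hat`, `ks_p`,
#'   `n_ratios`, `degenerate`.
#' @export
ratio_widths <- function(series, min_ratios = 50,
                         center = c("median", "mean")) {
  center <- match.arg(center)
  mat <- series_matrix(series)
  purrr::map_dfr(colnames(mat), function(sp) {
    x <- mat[, sp]
    ok <- x[-length(x)] > 0 & x[-1] > 0
    r <- x[-1][ok] / x[-length(x)][ok]
    out <- tibble::tibble(species = sp, mean_abundance = mean(x),
                          sigma_hat = NA_real_, ks_p = NA_real_,
                          n_ratios = length(r), degenerate = FALSE)
    if (length(r) < min_ratios) return(out)
    if (all(r == 1)) {
      out$sigma_hat <- 0; out$degenerate <- TRUE
      return(out)
    }
    s <- lognormal_width_mle(log(r), center)
    out$sigma_hat <- s
    ml <- if (center == "median") 0 else -s^2 / 2
    out$ks_p <- suppressWarnings(
      ks.test(r, plnorm, meanlog = ml, sdlog = s)$p.value
    )
    out
  })
}

#' Rank abundance profile
#'
#' Sorts time-averaged species abundances in decreasing order.  Heavy-tailed
#' (e.g. lognormal) profiles spanning several orders of magnitude are the
#' rule in real microbial communities.
#'
#' @param series an `abundance_series`.
#' @param per_time also return per-time-point profiles (to display the
#'   stability of the profile over time). Default `FALSE`.
#' @return A tibble `rank`, `species`, `mean_abundance`, non-increasing in
#'   rank; with `per_time = TRUE` an additional list-column-free long tibble
#'   attribute is attached as `attr(, "per_time")`.
#' @export
rank_abundance <- function(series, per_time = FALSE) {
  mat <- series_matrix(series)
  mu <- colMeans(mat)
  ord <- order(mu, decreasing = TRUE)
  out <- tibble::tibble(rank = seq_along(mu), species = colnames(mat)[ord],
                        mean_abundance = unname(mu[ord]))
  if (per_time) {
    pt <- purrr::map_dfr(seq_len(nrow(mat)), function(t) {
      tibble::tibble(time = series$time[t], rank = seq_along(mu),
                     abundance = sort(mat[t, ], decreasing = TRUE))
    })
    attr(out, "per_time") <- pt
  }
  out
}
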