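#' Blueprint for a synthetic heavy-tailed community
#'
#' A blueprint collects everything needed to draw a random community and
#' simulate it: the number of species, the steady-state generator, the
#' self-interaction generator, the off-diagonal interaction strength, the
#' noise mixture and the sampling scheme.  The defaults describe the
#' package's "stool-like" community: 100 species with lognormal steady states
#' spanning more than four decades (log10 sd 1.5 around a median of 100),
#' growth rates \eqn{g_i = |\omega_{ii}| x^*_i} placed in the white-pink
#' noise-color band at daily sampling (so the self-interactions, derived as
#' \eqn{-g_i/x^*_i}, span several decades, as noise-color inference on gut
#' data requires), and linear multiplicative noise strong enough that the
#' median successive-ratio width is of order one.
#'
#' @param S number of species.
#' @param x_star_log10_mean,x_star_log10_sd parameters of the lognormal
#'   steady-state generator (base-10 log scale). `x_star_log10_sd = 0` gives
#'   equal abundances.
#' @param self_mode how self-interactions are generated:
#'   * `"growth"` (default): growth rates are drawn log-uniformly with
#'     \eqn{\log_{10}(g\,\delta t)} over `growth_log10_range` -- the
#'     white-pink noise-color band at the blueprint's sampling interval --
#'     and the self-interactions follow as \eqn{\omega_{ii} = -g_i/x^*_i}.
#'     Because \eqn{x^*} spans several decades while \eqn{g} spans few, the
#'     self-interactions span decades and are anti-correlated with
#'     abundance, which is exactly what noise-color inference on real
#'     communities finds.
#'   * `"loguniform"`: self-interactions drawn directly as
#'     \eqn{\omega_{ii} = -10^u}, u uniform over `self_log10_range`,
#'     independent of \eqn{x^*} (growth rates then follow from the imposed
#'     fixed point and can span many decades; keep the ranges moderate).
#' @param growth_log10_range range of \eqn{\log_{10}(g \delta t)} for
#'   `self_mode = "growth"`.
#' @param self_log10_range range of \eqn{\log_{10}|\omega_{ii}|} for
#'   `self_mode = "loguniform"`.
#' @param alpha off-diagonal interaction standard deviation (0 = logistic
#'   model, no interspecies interactions).
#' @param sigma_lin,sigma_sqrt,sigma_add noise strengths, as in
#'   [noise_spec()].
#' @param delta_t sampling interval (time units; think days).
#' @param n_steps number of sampling intervals per simulated series.
#' @param max_tries rejection-sampling cap for feasible/stable draws when
#'   `alpha > 0`.
#' @return An object of class `community_blueprint`.
#' @export
community_blueprint <- function(S = 100,
                                x_star_log10_mean = 2,
                                x_star_log10_sd = 1.5,
                                self_mode = c("growth", "loguniform"),
                                growth_log10_range = c(-0.5, 1.5),
                                self_log10_range = c(-2.5, 0.5),
                                alpha = 0,
                                sigma_lin = 1.5,
                                sigma_sqrt = 0,
                                sigma_add = 0,
                                delta_t = 1,
                                n_steps = 1000,
                                max_tries = 20) {
  self_mode <- match.arg(self_mode)
  stopifnot(S >= 1, x_star_log10_sd >= 0, alpha >= 0,
            length(self_log10_range) == 2, length(growth_log10_range) == 2,
            delta_t > 0, n_steps >= 2)
  structure(
    list(S = S, x_star_log10_mean = x_star_log10_mean,
         x_star_log10_sd = x_star_log10_sd, self_mode = self_mode,
         growth_log10_range = sort(growth_log10_range),
         self_log10_range = sort(self_log10_range), alpha = alpha,
         sigma_lin = sigma_lin, sigma_sqrt = sigma_sqrt,
         sigma_add = sigma_add, delta_t = delta_t, n_steps = n_steps,
         max_tries = max_tries),
    class = "community_blueprint"
  )
}

#' @export
print.community_blueprint <- function(x, ...) {
  cat("<community_blueprint> S = ", x$S,
      ", x* ~ 10^N(", x$x_star_log10_mean, ", ", x$x_star_log10_sd, "^2)",
      if (x$self_mode == "growth") {
        sprintf(", g*dt ~ 10^U(%g, %g), w_ii = -g/x*",
                x$growth_log10_range[1], x$growth_log10_range[2])
      } else {
        sprintf(", |w_ii| ~ 10^U(%g, %g)", x$self_log10_range[1],
                x$self_log10_range[2])
      },
      ", alpha = ", x$alpha, "\n  noise (lin/sqrt/add) = ",
      x$sigma_lin, "/", x$sigma_sqrt, "/", x$sigma_add,
      ", delta_t = ", x$delta_t, ", n_steps = ", x$n_steps, "\n", sep = "")
  invisible(x)
}

# documented counter scheme: replicate k of base seed s gets its own stream
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

#' Draw a community from a blueprint
#'
#' Draws the steady state \eqn{x^*} (lognormal), the self-interactions
#' (log-uniform, negative), samples the off-diagonal interactions with
#' standard deviation `alpha`, and imposes the growth rates
#' \eqn{\hat g = -\omega x^*} so that \eqn{x^*} is a fixed point.  With
#' `alpha > 0`, draws whose fixed point is linearly unstable are rejected and
#' resampled up to `max_tries` times.
#'
#' @param blueprint a [community_blueprint()].
#' @param seed optional integer seed.
#' @return A list with elements `params` ([glv_params()]), `x_star`, and
#'   `noise` ([noise_spec()]).
#' @export
generate_community <- function(blueprint, seed = NULL) {
  stopifnot(inherits(blueprint, "community_blueprint"))
  if (!is.null(seed)) set.seed(seed)
  b <- blueprint
  for (try in seq_len(b$max_tries)) {
    x_star <- 10^rnorm(b$S, b$x_star_log10_mean, b$x_star_log10_sd)
    self <- if (b$self_mode == "growth") {
      g0 <- 10^runif(b$S, b$growth_log10_range[1], b$growth_log10_range[2]) /
        b$delta_t
      -g0 / x_star
    } else {
      -10^runif(b$S, b$self_log10_range[1], b$self_log10_range[2])
    }
    omega <- sample_interactions(b$S, b$alpha, self)
    g <- impose_growth(omega, x_star)
    params <- glv_params(g, omega)
    if (b$alpha == 0) break
    if (linear_stability(params, x_star)$stable) break
    if (try == b$max_tries) {
      stop("no stable feasible community found in ", b$max_tries, " draws")
    }
  }
  list(params = params, x_star = setNames(x_star, params$species),
       noise = noise_spec(b$sigma_lin, b$sigma_sqrt, b$sigma_add))
}

#' Simulate a community drawn from a blueprint
#'
#' [generate_community()] followed by [simulate_glv()] started at the fixed
#' point.
#'
#' @inheritParams generate_community
#' @return An `abundance_series`.
#' @export
simulate_community <- function(blueprint, seed = NULL) {
  com <- generate_community(blueprint, seed)
  simulate_glv(com$params, com$noise, t_max = blueprint$n_steps * blueprint$delta_t,
               delta_t = blueprint$delta_t, x0 = com$x_star)
}

#' Calibrate the noise-color curve
#'
#' For noninteracting species the fitted spectral slope depends only on the
#' product of self-interaction and mean abundance -- i.e. on the growth rate
#' \eqn{g = |\omega_{ii}|\,\bar x} -- and on the sampling interval.  This
#' function maps that dependence: for each grid value of
#' \eqn{\log_{10}(g\,\delta t)} it simulates `n_rep` independent logistic
#' species with small linear noise, fits their spectral slopes, and fits a
#' monotone (isotonic) curve through the per-point means.  Fast-relaxing
#' species sampled far above their corner frequency give flat (white)
#' spectra; slow ones approach the 1/f^2 (brown) limit of the
#' Ornstein-Uhlenbeck spectrum.
#'
#' The curve is bijective over its calibrated range and can therefore be
#' inverted by [infer_self_interactions()] to estimate self-interactions
#' from observed colors and mean abundances.
#'
#' @param log10_gdt_grid grid of \eqn{\log_{10}(g \delta t)} values.
#' @param n_rep independent species simulated per grid point.
#' @param delta_t sampling interval used for the calibration simulations.
#' @param n_steps series length (sampling intervals) per simulation.
#' @param sigma_lin linear noise strength used (the color does not depend on
#'   it; it only has to be positive).
#' @param seed optional integer seed.
#' @return An object of class `color_calibration`: tibble-backed list with
#'   the grid, per-point mean and sd of the slope, and the fitted monotone
#'   curve.
#' @export
calibrate_color_curve <- function(log10_gdt_grid = seq(-1.5, 2.5, by = 0.25),
                                  n_rep = 10, delta_t = 1, n_steps = 1000,
                                  sigma_lin = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- sort(log10_gdt_grid)
  g <- 10^grid / delta_t
  # one logistic community per replicate: one species per grid point, x* = 1
  params <- glv_params(growth = g, interactions = diag(-g, length(g)))
  slopes <- matrix(NA_real_, n_rep, length(g))
  for (r in seq_len(n_rep)) {
    ser <- simulate_glv(params, noise_spec(sigma_lin = sigma_lin),
                        t_max = n_steps * delta_t, delta_t = delta_t,
                        x0 = rep(1, length(g)))
    nc <- noise_color(ser)
    slopes[r, match(nc$species, params$species)] <- nc$slope
  }
  mean_slope <- colMeans(slopes, na.rm = TRUE)
  sd_slope <- apply(slopes, 2, sd, na.rm = TRUE)
  iso <- isoreg(grid, mean_slope)   # slope increases with g*dt (darker -> whiter)
  tbl <- tibble::tibble(log10_gdt = grid, mean_slope = mean_slope,
                        sd_slope = sd_slope, fitted_slope = iso$yf)
  if (any(diff(mean_slope) < -2 * sd_slope[-1])) {
    warning("raw mean slopes deviate from monotonicity beyond replicate scatter")
  }
  structure(list(table = tbl, delta_t = delta_t, n_rep = n_rep),
            class = "color_calibration")
}

#' @export
print.color_calibration <- function(x, ...) {
  rng <- range(x$table$fitted_slope)
  cat("<color_calibration> ", nrow(x$table), " grid points over log10(g dt) in [",
      min(x$table$log10_gdt), ", ", max(x$table$log10_gdt), "], slopes ",
      signif(rng[1], 3), " .. ", signif(rng[2], 3), "\n", sep = "")
  invisible(x)
}

#' @rdname calibrate_color_curve
#' @param x a `color_calibration` object.
#' @param ... unused.
#' @export
tidy.color_calibration <- function(x, ...) x$table

#' Infer self-interaction strengths from noise color
#'
#' Inverts a [calibrate_color_curve()] fit: given each species' fitted
#' spectral slope and mean abundance, reads off \eqn{\log_{10}(g\,\delta t)}
#' from the monotone calibration curve and converts it to a self-interaction
#' magnitude \eqn{|\omega_{ii}| = g / \bar x_i}.  The uncertainty of the
#' estimate is propagated from the calibration dispersion through the local
#' inverse derivative, so it inflates where the curve is flat (slopes near 0
#' and in the brown saturation region).  Species whose slope falls outside
#' the calibrated slope range, or lands where the curve is too flat to
#' invert (local gradient below `min_gradient` slope units per decade --
#' the white and brown saturation plateaus), are flagged `in_range = FALSE`
#' and their estimates withheld.
#'
#' @param colors a tibble as returned by [noise_color()] (columns `species`,
#'   `mean_abundance`, `slope`).
#' @param calibration a `color_calibration`.
#' @param delta_t sampling interval of the analyzed data (defaults to the
#'   calibration's own).
#' @param min_gradient smallest invertible curve gradient (slope units per
#'   decade of g dt); default 0.1.
#' @return A tibble: `species`, `mean_abundance`, `slope`, `log10_gdt`,
#'   `self_interaction` (negative, abundance^-1 time^-1 units),
#'   `log10_self_se`, `in_range`.
#' @export
infer_self_interactions <- function(colors, calibration, delta_t = NULL,
                                    min_gradient = 0.1) {
  stopifnot(inherits(calibration, "color_calibration"))
  if (is.null(delta_t)) delta_t <- calibration$delta_t
  tbl <- calibration$table
  # strictly increasing version of the fitted curve for inversion
  f <- tbl$fitted_slope + 1e-9 * seq_len(nrow(tbl))
  rng <- range(tbl$fitted_slope)
  inv <- approx(f, tbl$log10_gdt, xout = pmin(pmax(colors$slope, rng[1]), rng[2]),
                ties = "ordered")$y
  # local inverse derivative (decades of g*dt per unit slope)
  dgrid <- diff(tbl$log10_gdt)
  dslope <- pmax(diff(f), 1e-6)
  deriv <- approx(tbl$log10_gdt[-1] - dgrid / 2, dgrid / dslope, xout = inv,
                  rule = 2, ties = "ordered")$y
  disp <- approx(tbl$log10_gdt, tbl$sd_slope, xout = inv, rule = 2,
                 ties = "ordered")$y
  # at a saturated end of the curve (gradient below min_gradient) any slope
  # within the replicate scatter of the plateau is uninformative: the true
  # g dt could lie anywhere on the plateau, so the estimate is withheld
  n_tbl <- nrow(tbl)
  grad_lo <- (f[2] - f[1]) / (tbl$log10_gdt[2] - tbl$log10_gdt[1])
  grad_hi <- (f[n_tbl] - f[n_tbl - 1]) /
    (tbl$log10_gdt[n_tbl] - tbl$log10_gdt[n_tbl - 1])
  lo_cut <- if (grad_lo < min_gradient) rng[1] + 2 * tbl$sd_slope[1] else rng[1]
  hi_cut <- if (grad_hi < min_gradient) rng[2] - 2 * tbl$sd_slope[n_tbl] else rng[2]
  in_range <- colors$slope >= lo_cut & colors$slope <= hi_cut &
    1 / deriv >= min_gradient
  g <- 10^inv / delta_t
  out <- tibble::tibble(
    species = colors$species,
    mean_abundance = colors$mean_abundance,
    slope = colors$slope,
    log10_gdt = ifelse(in_range, inv, NA_real_),
    self_interaction = ifelse(in_range, -g / colors$mean_abundance, NA_real_),
    log10_self_se = ifelse(in_range, abs(deriv) * disp, NA_real_),
    in_range = in_range
  )
  out
}

#' Scan difference-scaling slope over the noise mixture
#'
#' For every combination of linear and square-root noise strengths on the
#' supplied grids, simulates replicate communities from the blueprint and
#' records the cross-species difference-scaling slope.  Pure linear noise
#' gives slope 1, pure square-root noise about 0.66, and mixtures
#' interpolate; with additive noise the slope drops to 0.
#'
#' @param blueprint a [community_blueprint()] (its own `sigma_*` fields are
#'   overridden by the grids).
#' @param sigma_lin_grid,sigma_sqrt_grid numeric vectors; the scan runs over
#'   their cross product.
#' @param n_rep replicates per grid cell.
#' @param seed base seed; replicate k of cell j uses a deterministic child
#'   seed.
#' @return A tidy tibble: `sigma_lin`, `sigma_sqrt`, `replicate`, `seed`,
#'   `slope`.
#' @export
scan_noise_mix <- function(blueprint, sigma_lin_grid = c(0, 1.5),
                           sigma_sqrt_grid = c(0, 7),
                           n_rep = 5, seed = 1) {
  cells <- tidyr::expand_grid(sigma_lin = sigma_lin_grid,
                              sigma_sqrt = sigma_sqrt_grid)
  cells$cell <- seq_len(nrow(cells))
  purrr::pmap_dfr(cells, function(sigma_lin, sigma_sqrt, cell) {
    purrr::map_dfr(seq_len(n_rep), function(k) {
      b <- blueprint
      b$sigma_lin <- sigma_lin; b$sigma_sqrt <- sigma_sqrt; b$sigma_add <- 0
      sk <- child_seed(seed, 1000 * cell + k)
      ser <- simulate_community(b, seed = sk)
      # degenerate cells (e.g. the noiseless corner of the grid) yield NA
      sl <- tryCatch(suppressWarnings(glance(difference_scaling(ser))$slope),
                     error = function(e) NA_real_)
      tibble::tibble(sigma_lin = sigma_lin, sigma_sqrt = sigma_sqrt,
                     replicate = k, seed = sk, slope = sl)
    })
  })
}

#' Scan ratio-distribution width over the noise strength
#'
#' Simulates replicate communities at each linear-noise strength and records
#' the median fitted lognormal width of the successive-abundance ratios and
#' the median Kolmogorov-Smirnov p-value.  The width grows monotonically
#' with the noise strength; for sufficiently strong noise the lognormal fit
#' is good (high p).
#'
#' @inheritParams scan_noise_mix
#' @param sigma_grid linear-noise strengths to scan.
#' @return A tidy tibble: `sigma_lin`, `replicate`, `seed`, `median_width`,
#'   `median_ks_p`.
#' @export
scan_ratio_width <- function(blueprint, sigma_grid, n_rep = 3, seed = 1) {
  purrr::imap_dfr(sigma_grid, function(sg, j) {
    purrr::map_dfr(seq_len(n_rep), function(k) {
      b <- blueprint
      b$sigma_lin <- sg; b$sigma_sqrt <- 0; b$sigma_add <- 0
      sk <- child_seed(seed, 1000 * j + k)
      ser <- simulate_community(b, seed = sk)
      rw <- ratio_widths(ser)
      tibble::tibble(sigma_lin = sg, replicate = k, seed = sk,
                     median_width = median(rw$sigma_hat, na.rm = TRUE),
                     median_ks_p = median(rw$ks_p, na.rm = TRUE))
    })
  })
}

#' Full stochastic-logistic community study
#'
#' Simulates `n_rep` independent communities from the blueprint and computes
#' the complete characterization bundle for each: rank abundance profile,
#' per-species noise colors, the cross-species difference-scaling slope,
#' successive-ratio widths, the Kullback-Leibler distance to neutrality and
#' (optionally) the neutral covariance test.  The headline summary is the
#' niche fraction: the proportion of replicates whose NCT p-value falls
#' below `alpha`, which for the default heavy-tailed blueprint with strong
#' linear noise is well above one half even though the model contains no
#' interactions at all.
#'
#' @inheritParams scan_noise_mix
#' @param n_rep number of replicate communities.
#' @param nct run the neutral covariance test per replicate (default TRUE).
#' @param n_partitions,n_null NCT settings, see [neutral_covariance_test()].
#' @param alpha significance level for the niche label.
#' @return An object of class `community_study`: list with tibbles
#'   `replicates` (one row per replicate: seed, diff-scaling slope,
#'   median width, KL divergence, NCT p), `colors` (per replicate x species)
#'   and scalars `niche_fraction`, `n_rep`.
#' @export
run_community_study <- function(blueprint, n_rep = 20, nct = TRUE,
                                n_partitions = 60, n_null = 100,
                                alpha = 0.05, seed = 1) {
  colors <- list(); reps <- list()
  for (k in seq_len(n_rep)) {
    sk <- child_seed(seed, k)
    ser <- simulate_community(blueprint, seed = sk)
    nc <- noise_color(ser)
    ds <- suppressWarnings(difference_scaling(ser))
    rw <- ratio_widths(ser)
    kl <- kl_neutrality(ser)
    p <- if (nct) {
      neutral_covariance_test(ser, n_partitions, n_null,
                              seed = child_seed(sk, 1))$p.value
    } else NA_real_
    colors[[k]] <- dplyr::mutate(nc, replicate = k, .before = 1)
    reps[[k]] <- tibble::tibble(
      replicate = k, seed = sk, slope = ds$slope,
      median_width = median(rw$sigma_hat, na.rm = TRUE),
      median_ks_p = median(rw$ks_p, na.rm = TRUE),
      kl_divergence = kl, nct_p = p
    )
  }
  reps <- dplyr::bind_rows(reps)
  structure(
    list(replicates = reps, colors = dplyr::bind_rows(colors),
         niche_fraction = if (nct) mean(reps$nct_p < alpha) else NA_real_,
         n_rep = n_rep, alpha = alpha, blueprint = blueprint),
    class = "community_study"
  )
}

#' @export
print.community_study <- function(x, ...) {
  cat("<community_study> ", x$n_rep, " replicates\n", sep = "")
  cat("  mean diff-scaling slope: ", signif(mean(x$replicates$slope), 3), "\n",
      "  median ratio width:      ", signif(median(x$replicates$median_width), 3), "\n",
      "  median KL divergence:    ", signif(median(x$replicates$kl_divergence), 3), "\n",
      sep = "")
  if (!is.na(x$niche_fraction)) {
    cat("  niche fraction (NCT p < ", x$alpha, "): ", x$niche_fraction, "\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname run_community_study
#' @param x a `community_study` object.
#' @param ... unused.
#' @export
glance.community_study <- function(x, ...) {
  tibble::tibble(
    n_rep = x$n_rep,
    mean_slope = mean(x$replicates$slope),
    median_width = median(x$replicates$median_width),
    median_kl = median(x$replicates$kl_divergence),
    niche_fraction = x$niche_fraction
  )
}

#' @rdname run_community_study
#' @export
tidy.community_study <- function(x, ...) x$replicates
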