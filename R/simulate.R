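#' Specify the stochastic forcing of a simulation
#'
#' Three independent noise channels act on every species, each with its own
#' strength and its own Brownian motion:
#' * **linear multiplicative** (`sigma_lin`, 1/sqrt(time)): term
#'   \eqn{\sigma_i x_i\,dW}; models extrinsic growth-rate fluctuations from a
#'   changing environment.
#' * **square-root** (`sigma_sqrt`, sqrt(abundance)/sqrt(time)): term
#'   \eqn{\sigma_{i,\mathrm{sqrt}} \sqrt{x_i}\,dW}; demographic (intrinsic)
#'   noise from Poisson birth-death statistics.  Because that derivation
#'   assumes integer counts, the channel is suppressed whenever a species'
#'   abundance drops below one (see [simulate_glv()]).
#' * **additive** (`sigma_add`, abundance/sqrt(time)): term
#'   \eqn{\sigma_{i,\mathrm{const}}\,dW}; fluctuating immigration.
#'
#' @param sigma_lin,sigma_sqrt,sigma_add non-negative numeric vectors
#'   (scalars are broadcast across species).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_lin = 0, sigma_sqrt = 0, sigma_add = 0) {
  for (nm in c("sigma_lin", "sigma_sqrt", "sigma_add")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("`", nm, "` must be finite and non-negative")
    }
  }
  structure(list(sigma_lin = sigma_lin, sigma_sqrt = sigma_sqrt,
                 sigma_add = sigma_add),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec> lin:", paste(signif(unique(x$sigma_lin), 3), collapse = "/"),
      " sqrt:", paste(signif(unique(x$sigma_sqrt), 3), collapse = "/"),
      " add:", paste(signif(unique(x$sigma_add), 3), collapse = "/"), "\n")
  invisible(x)
}

broadcast_sigma <- function(v, S, name) {
  if (length(v) == 1) v <- rep(v, S)
  if (length(v) != S) stop("`", name, "` must have length 1 or S = ", S)
  as.numeric(v)
}

#' Coerce a data frame to an abundance series
#'
#' An abundance series is a tibble with a `time` column (uniformly spaced)
#' followed by one non-negative numeric column per species, carrying the
#' sampling interval `delta_t` as an attribute.  All characterization
#' functions in the package consume this shape.
#'
#' @param x a data frame with a time column and species columns.
#' @param time_col name of the time column. Default `"time"`.
#' @return A tibble of class `abundance_series`.
#' @export
as_abundance_series <- function(x, time_col = "time") {
  x <- tibble::as_tibble(x)
  if (!time_col %in% names(x)) stop("no `", time_col, "` column found")
  if (time_col != "time") names(x)[names(x) == time_col] <- "time"
  x <- dplyr::relocate(x, "time")
  if (ncol(x) < 2) stop("series must contain at least one species column")
  vals <- as.matrix(x[, -1])
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("species columns must be numeric with no missing values")
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at row ", bad[1], ", species column ", bad[2])
  }
  dt <- diff(x$time)
  if (length(dt) < 1 || any(dt <= 0)) stop("time must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * abs(mean(dt))) {
    stop("time points must be uniformly spaced (relative tolerance 1e-6)")
  }
  attr(x, "delta_t") <- mean(dt)
  class(x) <- c("abundance_series", class(x))
  x
}

#' Sampling interval of an abundance series
#' @param series an `abundance_series`.
#' @return The sampling interval `delta_t`.
#' @export
sampling_interval <- function(series) {
  dt <- attr(series, "delta_t")
  if (is.null(dt)) dt <- mean(diff(series$time))
  dt
}

#' Species abundance matrix of a series
#' @param series an `abundance_series` (or any tibble with a time column).
#' @return A time x species numeric matrix.
#' @export
series_matrix <- function(series) {
  as.matrix(series[, setdiff(names(series), "time"), drop = FALSE])
}

new_abundance_series <- function(times, mat, species, delta_t, seed = NULL) {
  colnames(mat) <- species
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(tibble::tibble(time = times), out)
  attr(out, "delta_t") <- delta_t
  attr(out, "seed") <- seed
  class(out) <- c("abundance_series", class(out))
  out
}

#' Simulate stochastic gLV dynamics
#'
#' Integrates the gLV equations with the noise channels of [noise_spec()] by
#' fixed-step Euler-Maruyama: per internal step `dt`,
#' \deqn{\Delta x_i = (\lambda_i + g_i x_i + \textstyle\sum_j \omega_{ij} x_i
#'   x_j)\,dt + \sigma_i x_i \sqrt{dt}\,\eta + \sigma_{i,\mathrm{sqrt}}
#'   \sqrt{x_i}\sqrt{dt}\,\eta' + \sigma_{i,\mathrm{const}}\sqrt{dt}\,\eta'',}
#' with independent standard normal draws per species and channel.  States are
#' clipped at zero after every step (abundances cannot be negative), and the
#' square-root channel is switched off for species below abundance one, where
#' its Poisson-statistics derivation does not apply.
#'
#' The trajectory is recorded every `delta_t` time units; the integration step
#' defaults to `delta_t/100`, refined automatically so that
#' `max(|g|) * dt <= 0.05` keeps stiff (fast-relaxing) species accurate.
#'
#' @param params a [glv_params()] object.
#' @param noise a [noise_spec()]. Default: no noise.
#' @param t_max total simulated time after the transient.
#' @param delta_t sampling interval of the recorded series.
#' @param dt integration step; `NULL` (default) chooses it as described above.
#' @param x0 initial state: numeric vector or `"steady_state"` (the default)
#'   to start at the solved fixed point.
#' @param transient time to integrate and discard before recording (default 0;
#'   simulations started at the fixed point need none).
#' @param seed optional integer seed.
#' @return An `abundance_series` tibble with `floor(t_max/delta_t) + 1` rows.
#' @examples
#' p <- glv_params(growth = 5, interactions = matrix(-1))
#' s <- simulate_glv(p, noise_spec(sigma_lin = 0.3), t_max = 200, seed = 1)
#' head(s)
#' @export
simulate_glv <- function(params, noise = noise_spec(), t_max, delta_t = 1,
                         dt = NULL, x0 = "steady_state", transient = 0,
                         seed = NULL) {
  stopifnot(inherits(params, "glv_params"), inherits(noise, "noise_spec"))
  S <- params$S
  if (identical(x0, "steady_state")) {
    x0 <- solve_steady_state(params)
  }
  if (length(x0) != S) stop("`x0` must have length S = ", S)
  if (any(x0 < 0)) stop("initial abundances must be non-negative")
  if (delta_t <= 0 || t_max < delta_t) stop("need 0 < delta_t <= t_max")

  if (is.null(dt)) {
    # fastest per-species relaxation rate near the initial state
    rates <- abs(params$interactions) %*% x0
    gmax <- max(abs(params$growth), rates, 1e-12)
    dt_target <- min(delta_t / 100, 0.05 / gmax)
    thin <- as.integer(ceiling(delta_t / dt_target))
  } else {
    thin <- as.integer(round(delta_t / dt))
    if (thin < 1 || abs(thin * dt - delta_t) > 1e-8 * delta_t) {
      stop("`delta_t` must be an integer multiple of `dt`")
    }
  }
  dt_eff <- delta_t / thin
  n_keep <- as.integer(floor((t_max - 0) / delta_t))
  n_burn <- as.integer(round(transient / dt_eff))

  sl <- broadcast_sigma(noise$sigma_lin, S, "sigma_lin")
  ss <- broadcast_sigma(noise$sigma_sqrt, S, "sigma_sqrt")
  sa <- broadcast_sigma(noise$sigma_add, S, "sigma_add")

  if (!is.null(seed)) set.seed(seed)
  mat <- em_integrate(as.numeric(x0), params$growth, params$interactions,
                      params$immigration, sl, ss, sa, dt_eff, thin, n_keep,
                      n_burn,
                      diagonal_only = all(params$interactions[
                        row(params$interactions) != col(params$interactions)] == 0))
  times <- transient + delta_t * (0:n_keep)
  new_abundance_series(times, mat, params$species, delta_t, seed)
}

#' Convert a series to relative abundances
#'
#' Divides every row by its total, so rows sum to one.  Because the total
#' abundance of a stochastic logistic community with linear noise stays nearly
#' constant relative to per-species fluctuations, characterizations are
#' essentially unchanged by this transform, which is what makes
#' compositional (sequencing-derived) data tractable with these tools.
#'
#' @param series an `abundance_series`.
#' @return An `abundance_series` of relative abundances.
#' @export
to_relative <- function(series) {
  mat <- series_matrix(series)
  tot <- rowSums(mat)
  if (any(tot <= 0)) stop("row ", which(tot <= 0)[1], " has zero total abundance")
  new_abundance_series(series$time, mat / tot, colnames(mat),
                       sampling_interval(series))
}

#' @export
print.abundance_series <- function(x, ...) {
  cat("<abundance_series> ", nrow(x), " time points x ", ncol(x) - 1,
      " species, delta_t = ", signif(sampling_interval(x), 4), "\n", sep = "")
  NextMethod()
}
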