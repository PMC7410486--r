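# shared fixtures and independent oracles, built in code at test time

# closed-form spectrum of a sampled (aliased) Ornstein-Uhlenbeck process:
# an AR(1) with autoregression exp(-g * delta_t).  Fitting its log-log slope
# over the same frequency band as the estimator gives an independent
# prediction for the noise color of a linearized logistic species.
ou_theory_slope <- function(log10_gdt, n = 1000, delta_t = 1,
                            cutoff_decades = 1) {
  phi <- exp(-10^log10_gdt * delta_t)
  k <- seq_len(floor(n / 2))
  f <- k / (n * delta_t)
  power <- (1 - phi^2) / (1 - 2 * phi * cos(2 * pi * f * delta_t) + phi^2)
  psd_slope(f, power, cutoff_decades)
}

# small logistic community: S independent species, x* = 1, growth rates g
logistic_params <- function(g, x_star = rep(1, length(g))) {
  glv_params(growth = g, interactions = diag(-g / x_star, length(g)))
}

# quick stool-like blueprint scaled for unit tests
test_blueprint <- function(S = 30, n_steps = 400, ...) {
  community_blueprint(S = S, n_steps = n_steps, ...)
}

# series built directly from a matrix
series_from_matrix <- function(mat, delta_t = 1) {
  colnames(mat) <- sprintf("sp%02d", seq_len(ncol(mat)))
  as_abundance_series(
    tibble::tibble(time = delta_t * (seq_len(nrow(mat)) - 1)) |>
      dplyr::bind_cols(tibble::as_tibble(as.data.frame(mat)))
  )
}
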