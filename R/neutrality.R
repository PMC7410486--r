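#' Gaussian summary of a community series
#'
#' Sample mean vector and covariance matrix of the species abundances across
#' time, summarizing the community as a multivariate Gaussian.  This is the
#' ingredient of the Kullback-Leibler neutrality measure.
#'
#' @param series an `abundance_series` with >= 3 time points (a warning is
#'   issued when there are fewer time points than species, where the sample
#'   covariance is rank-deficient).
#' @param relative summarize relative abundances instead of absolute ones.
#' @return An object of class `gaussian_summary`: list with `mean` (length
#'   S), `cov` (S x S), `n` (time points).
#' @export
gaussian_summary <- function(series, relative = FALSE) {
  if (relative) series <- to_relative(series)
  mat <- series_matrix(series)
  if (nrow(mat) < 3) stop("need at least 3 time points")
  if (nrow(mat) <= ncol(mat)) {
    warning("fewer time points than species: covariance is rank-deficient")
  }
  structure(list(mean = colMeans(mat), cov = cov(mat), n = nrow(mat)),
            class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat("<gaussian_summary> ", length(x$mean), " species, ", x$n,
      " time points\n", sep = "")
  invisible(x)
}

#' Project a Gaussian summary onto the neutral (exchangeable) manifold
#'
#' Under ecological neutrality all species are statistically equivalent, so
#' the community Gaussian must be exchangeable: equal means, equal variances,
#' equal covariances.  The projection averages the observed quantities:
#' \deqn{\mu_N = S^{-1}\sum_i \mu_i,\quad K_{N,ii} = S^{-1}\sum_i K_{ii},
#'   \quad K_{N,ij} = \frac{1}{S(S-1)}\sum_i \sum_{j \ne i} K_{ij}.}
#' The projection is idempotent and invariant under species permutation.
#'
#' @param summary a [gaussian_summary()] with S >= 2.
#' @return A `gaussian_summary` of the matched neutral community.
#' @export
neutral_projection <- function(summary) {
  stopifnot(inherits(summary, "gaussian_summary"))
  S <- length(summary$mean)
  if (S < 2) stop("neutral projection requires at least 2 species")
  K <- summary$cov
  off <- K[row(K) != col(K)]
  KN <- matrix(mean(off), S, S)
  diag(KN) <- mean(diag(K))
  structure(list(mean = rep(mean(summary$mean), S), cov = KN, n = summary$n),
            class = "gaussian_summary")
}

regularize_cov <- function(K, epsilon = 1e-8) {
  K + diag(epsilon * mean(diag(K)), nrow(K))
}

#' Kullback-Leibler divergence between two Gaussian summaries
#'
#' Closed form for multivariate Gaussians,
#' \deqn{D_{KL}(P\|Q) = \tfrac12\Big(\ln\frac{\det K_Q}{\det K_P} - n +
#'   \mathrm{Tr}(K_Q^{-1} K_P) + (\mu_Q-\mu_P)^T K_Q^{-1}(\mu_Q-\mu_P)\Big).}
#' `K_Q` is regularized by adding `epsilon * mean(diag(K_Q))` to its diagonal
#' before inversion when it is not positive definite, which long series of
#' near-collinear species otherwise provoke.
#'
#' @param P,Q [gaussian_summary()] objects of equal dimension.
#' @param epsilon ridge fraction for the regularization fallback.
#' @return Non-negative divergence in nats (0 iff P = Q).
#' @export
kl_gaussian <- function(P, Q, epsilon = 1e-8) {
  stopifnot(inherits(P, "gaussian_summary"), inherits(Q, "gaussian_summary"))
  n <- length(P$mean)
  if (length(Q$mean) != n) stop("dimension mismatch between P and Q")
  KP <- P$cov
  KQ <- Q$cov
  chQ <- tryCatch(chol(KQ), error = function(e) NULL)
  if (is.null(chQ)) {
    KQ <- regularize_cov(KQ, epsilon)
    chQ <- tryCatch(chol(KQ), error = function(e)
      stop("K_Q is not positive definite even after regularization"))
  }
  KQinv <- chol2inv(chQ)
  ldQ <- 2 * sum(log(diag(chQ)))
  chP <- tryCatch(chol(KP), error = function(e) NULL)
  if (is.null(chP)) chP <- chol(regularize_cov(KP, epsilon))
  ldP <- 2 * sum(log(diag(chP)))
  dmu <- Q$mean - P$mean
  d <- 0.5 * (ldQ - ldP - n + sum(diag(KQinv %*% KP)) +
                as.numeric(t(dmu) %*% KQinv %*% dmu))
  max(d, 0)
}

#' Kullback-Leibler distance to neutrality
#'
#' \eqn{D_{KL}(P \| P_N)} between the community's Gaussian summary and its
#' neutral (exchangeable) projection.  Zero exactly when the summary is
#' already exchangeable; grows with the spread of species means and with
#' structure in the covariances, i.e. with the community's niche character.
#'
#' @inheritParams gaussian_summary
#' @param epsilon regularization passed to [kl_gaussian()].
#' @return Non-negative divergence (nats).
#' @export
kl_neutrality <- function(series, relative = FALSE, epsilon = 1e-8) {
  P <- gaussian_summary(series, relative = relative)
  kl_gaussian(P, neutral_projection(P), epsilon = epsilon)
}

#' Simulate a Wright-Fisher community
#'
#' Multinomial-resampling drift of relative abundances in a community of
#' fixed size: \eqn{f(t+\delta t) \sim \mathrm{Multinomial}(N, f(t))/N}.
#' This is the continuous-time-limit null model of neutral dynamics used by
#' the neutral covariance test: every group of species drifts with variance
#' \eqn{f_A(1-f_A)/N}, whatever the grouping.
#'
#' @param init_freq initial relative abundances (positive, summing to one
#'   after normalization).
#' @param n_individuals community size N (variance scale of the drift).
#' @param n_steps number of sampling steps.
#' @param delta_t nominal sampling interval of the returned series.
#' @param seed optional integer seed.
#' @return An `abundance_series` of relative abundances with
#'   `n_steps + 1` rows.
#' @export
wright_fisher_series <- function(init_freq, n_individuals, n_steps,
                                 delta_t = 1, seed = NULL) {
  if (any(init_freq < 0) || sum(init_freq) <= 0) {
    stop("`init_freq` must be non-negative with positive total")
  }
  f0 <- init_freq / sum(init_freq)
  if (!is.null(seed)) set.seed(seed)
  mat <- wright_fisher_steps(f0, n_individuals, n_steps)
  sp <- names(init_freq)
  if (is.null(sp)) sp <- sprintf("sp%0*d", max(2L, nchar(length(f0))),
                                 seq_along(f0))
  new_abundance_series(delta_t * (0:n_steps), mat, sp, delta_t, seed)
}

random_bipartitions <- function(S, n_partitions) {
  parts <- matrix(FALSE, n_partitions, S)
  for (k in seq_len(n_partitions)) {
    repeat {
      grp <- runif(S) < 0.5
      if (any(grp) && !all(grp)) break
    }
    parts[k, ] <- grp
  }
  parts
}

# scaled increment variance of one grouped share: mean of
# (f_A(t+dt) - f_A(t))^2 / (f_A(t)(1 - f_A(t))); under Wright-Fisher drift of
# community size N this estimates 1/N for every grouping A.
scaled_group_variance <- function(fa_now, fa_next) {
  den <- fa_now * (1 - fa_now)
  use <- den > 0
  if (!any(use)) return(NA_real_)
  mean((fa_next[use] - fa_now[use])^2 / den[use])
}

nct_dispersion <- function(v) {
  v <- v[is.finite(v) & v > 0]
  if (length(v) < 3) return(NA_real_)
  sd(log(v))
}

#' Neutral covariance test
#'
#' Tests whether a community time series is consistent with neutral
#' Wright-Fisher drift by probing its grouping invariance.  Under a
#' Wright-Fisher process of community size N, the aggregated share
#' \eqn{f_A} of *any* group A of species has one-step increment variance
#' \eqn{f_A(1-f_A)/N}; the scaled increment variance is therefore the same
#' constant for every grouping.  The test statistic is the dispersion (sd of
#' the log) of the scaled increment variances across `n_partitions` random
#' bipartitions of the species.
#'
#' Its null distribution comes from a conditional parametric bootstrap:
#' the community size is estimated from the data's own pooled scaled
#' increment variance (\eqn{\hat N = 1/\bar v}), and each null replicate
#' redraws every one-step transition as a multinomial Wright-Fisher step
#' \eqn{f(t+\delta t) \sim \mathrm{Multinomial}(\hat N, f_{obs}(t))/\hat N}
#' from the observed state, then recomputes the statistic on the same
#' bipartitions.  Conditioning on the observed states makes the null exactly
#' calibrated when the data are Wright-Fisher (the rejection rate at level
#' \eqn{\alpha} is \eqn{\alpha}) and avoids the absorption pathologies of
#' free-running drift when the estimated community size is small.  Small
#' p-values reject neutrality: some groupings fluctuate more than their
#' share allows, the signature of the niche regime.
#'
#' The series is converted to relative abundances internally.
#'
#' @param series an `abundance_series` with >= 3 species and >= 10 time
#'   points.
#' @param n_partitions random species bipartitions per statistic (default
#'   100).
#' @param n_null null bootstrap replicates (default 200).
#' @param seed optional integer seed.
#' @return An object of class `glv_nct` with elements `statistic`,
#'   `p.value`, `n_hat`, `n_partitions`, `n_null`; `tidy()` returns it as a
#'   one-row tibble.
#' @export
neutral_covariance_test <- function(series, n_partitions = 100, n_null = 200,
                                    seed = NULL) {
  fmat <- series_matrix(to_relative(series))
  S <- ncol(fmat)
  Tn <- nrow(fmat)
  if (S < 3) stop("the neutral covariance test needs at least 3 species")
  if (Tn < 10) stop("the neutral covariance test needs at least 10 time points")
  if (!is.null(seed)) set.seed(seed)
  parts <- random_bipartitions(S, n_partitions)

  v_obs <- vapply(seq_len(n_partitions), function(k) {
    fa <- rowSums(fmat[, parts[k, ], drop = FALSE])
    scaled_group_variance(fa[-Tn], fa[-1])
  }, numeric(1))
  stat_obs <- nct_dispersion(v_obs)
  if (!is.finite(stat_obs)) stop("degenerate series: grouping statistic undefined")

  # matched drift scale: pooled scaled increment variance estimates 1/N
  n_hat <- min(max(round(1 / mean(v_obs, na.rm = TRUE)), 10), 1e9)

  # one-step multinomial transitions from each observed state
  # draws[, rep, t] is the resampled composition following f_obs(t)
  draws <- array(NA_real_, c(S, n_null, Tn - 1))
  for (t in seq_len(Tn - 1)) {
    p <- pmax(fmat[t, ], 0)
    draws[, , t] <- rmultinom(n_null, n_hat, p) / n_hat
  }
  # v_null[k, r]: statistic ingredients for partition k under null replicate r
  v_null <- matrix(NA_real_, n_partitions, n_null)
  for (k in seq_len(n_partitions)) {
    grp <- parts[k, ]
    fa_now <- rowSums(fmat[-Tn, grp, drop = FALSE])
    den <- fa_now * (1 - fa_now)
    use <- den > 0
    if (!any(use)) next
    ga <- colSums(draws[grp, , , drop = FALSE], dims = 1)  # n_null x (Tn-1)
    dev2 <- sweep(ga, 2, fa_now)^2
    v_null[k, ] <- rowMeans(sweep(dev2[, use, drop = FALSE], 2, den[use], "/"))
  }
  null_stats <- apply(v_null, 2, nct_dispersion)
  null_stats <- null_stats[is.finite(null_stats)]

  p <- (1 + sum(null_stats >= stat_obs)) / (length(null_stats) + 1)
  structure(list(statistic = stat_obs, p.value = p, n_hat = n_hat,
                 n_partitions = n_partitions, n_null = length(null_stats)),
            class = "glv_nct")
}

#' @export
print.glv_nct <- function(x, ...) {
  cat("Neutral covariance test\n")
  cat("  grouping-dispersion statistic:", signif(x$statistic, 4), "\n")
  cat("  matched community size N:", signif(x$n_hat, 4), "\n")
  cat("  p-value:", signif(x$p.value, 4),
      if (x$p.value < 0.05) "(niche regime)" else "(consistent with neutrality)",
      "\n")
  invisible(x)
}

#' @rdname neutral_covariance_test
#' @param x a `glv_nct` object.
#' @param ... unused.
#' @export
tidy.glv_nct <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n_hat = x$n_hat, n_partitions = x$n_partitions,
                 n_null = x$n_null)
}

#' Combined neutrality summary of a series
#'
#' Convenience wrapper computing both neutrality measures: the
#' Kullback-Leibler distance to the exchangeable projection and the neutral
#' covariance test p-value.
#'
#' @inheritParams neutral_covariance_test
#' @param relative use relative abundances for the KL measure (the NCT always
#'   works on relative abundances).
#' @param alpha significance level for the niche label (default 0.05).
#' @return A one-row tibble: `kl_divergence`, `nct_p`, `nct_label`.
#' @export
neutrality_measures <- function(series, relative = FALSE, n_partitions = 100,
                                n_null = 200, alpha = 0.05, seed = NULL) {
  kl <- kl_neutrality(series, relative = relative)
  nct <- neutral_covariance_test(series, n_partitions, n_null, seed)
  tibble::tibble(
    kl_divergence = kl, nct_p = nct$p.value,
    nct_label = ifelse(nct$p.value < alpha, "niche", "neutral")
  )
}
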