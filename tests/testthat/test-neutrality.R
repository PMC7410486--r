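test_that("gaussian summaries capture exact dependence structure", {
  set.seed(1)
  z <- rnorm(200)
  # two perfectly correlated species attain the correlation bound
  s <- series_from_matrix(cbind(10 + z, 25 + 3 * z))
  gs <- gaussian_summary(s)
  expect_equal(gs$cov[1, 2], sqrt(gs$cov[1, 1] * gs$cov[2, 2]))

  # independent white-noise species: off-diagonals vanish within se ~ 1/sqrt(T)
  m <- matrix(rnorm(5 * 2000, mean = 10), 2000, 5)
  gs2 <- gaussian_summary(series_from_matrix(m))
  off <- gs2$cov[row(gs2$cov) != col(gs2$cov)]
  expect_lt(max(abs(off)), 4 / sqrt(2000))

  # constant series has a zero covariance matrix
  gs3 <- gaussian_summary(series_from_matrix(matrix(1, 10, 3)))
  expect_equal(unname(gs3$cov), matrix(0, 3, 3))

  expect_error(gaussian_summary(series_from_matrix(matrix(1:4, 2, 2))), "3 time")
  expect_warning(gaussian_summary(series_from_matrix(matrix(runif(12), 3, 4))),
                 "rank-deficient")
})

test_that("the neutral projection averages, is idempotent and permutation invariant", {
  gs <- structure(list(mean = c(1, 3),
                       cov = matrix(c(2, 0.5, 0.5, 4), 2, 2), n = 50),
                  class = "gaussian_summary")
  pn <- neutral_projection(gs)
  expect_equal(pn$mean, c(2, 2))
  expect_equal(unname(diag(pn$cov)), c(3, 3))
  expect_equal(pn$cov[1, 2], 0.5)

  expect_equal(neutral_projection(pn), pn)

  set.seed(2)
  m <- matrix(rlnorm(6 * 100), 100, 6)
  perm <- sample(6)
  p1 <- neutral_projection(gaussian_summary(series_from_matrix(m)))
  p2 <- neutral_projection(gaussian_summary(series_from_matrix(m[, perm])))
  expect_equal(p1$mean, p2$mean)
  expect_equal(p1$cov, p2$cov)

  expect_error(neutral_projection(gaussian_summary(
    series_from_matrix(matrix(runif(10), 10, 1)))), "2 species")
})

test_that("gaussian KL divergence matches scalar and separable closed forms", {
  gsum <- function(mu, K) structure(list(mean = mu, cov = as.matrix(K),
                                         n = 100), class = "gaussian_summary")
  # identity case
  P <- gsum(c(1, 2), diag(c(2, 3)))
  expect_identical(kl_gaussian(P, P), 0)

  # scalar closed form: N(0,1) vs N(1,1) -> 1/2
  expect_equal(kl_gaussian(gsum(0, 1), gsum(1, 1)), 0.5, tolerance = 1e-12)
  # general scalar oracle
  kl1 <- function(muP, s2P, muQ, s2Q) {
    0.5 * (log(s2Q / s2P) - 1 + s2P / s2Q + (muQ - muP)^2 / s2Q)
  }
  expect_equal(kl_gaussian(gsum(0.3, 0.7), gsum(-1, 2.2)),
               kl1(0.3, 0.7, -1, 2.2), tolerance = 1e-12)

  # diagonal bivariate case separates into the sum of scalar divergences
  P2 <- gsum(c(0, 1), diag(c(1, 2)))
  Q2 <- gsum(c(1, -1), diag(c(2, 1)))
  expect_equal(kl_gaussian(P2, Q2),
               kl1(0, 1, 1, 2) + kl1(1, 2, -1, 1), tolerance = 1e-12)

  # non-negative on random summaries
  set.seed(3)
  for (i in 1:5) {
    A <- crossprod(matrix(rnorm(9), 3)) + diag(0.1, 3)
    B <- crossprod(matrix(rnorm(9), 3)) + diag(0.1, 3)
    expect_gte(kl_gaussian(gsum(rnorm(3), A), gsum(rnorm(3), B)), 0)
  }
})

test_that("KL neutrality vanishes for exchangeable communities and grows with spread", {
  # i.i.d. identical species: divergence shrinks as the series grows
  set.seed(4)
  kl_at <- function(T) {
    m <- matrix(rnorm(6 * T, mean = 10), T, 6)
    kl_neutrality(series_from_matrix(m))
  }
  kls <- sapply(c(100, 400, 1600, 6400), kl_at)
  expect_lt(kls[4], kls[1])
  expect_lt(kls[4], 0.05)

  # widening the spread of species means increases the divergence
  m0 <- matrix(rnorm(4 * 500, mean = 10), 500, 4)
  spread <- c(0, 4, 8)
  kl_spread <- sapply(spread, function(d) {
    kl_neutrality(series_from_matrix(sweep(m0, 2, d * (1:4), "+")))
  })
  expect_true(all(diff(kl_spread) > 0))
})

test_that("the neutral covariance test is calibrated on Wright-Fisher drift", {
  set.seed(5)
  f0 <- { x <- 10^rnorm(20, 0, 0.8); x / sum(x) }
  ps <- sapply(1:25, function(k) {
    ser <- wright_fisher_series(f0, 3000, 250, seed = 900 + k)
    neutral_covariance_test(ser, n_partitions = 40, n_null = 60,
                            seed = k)$p.value
  })
  # no excess rejection at the 5% level (binomial: at most ~4 of 25)
  expect_lte(sum(ps < 0.05), 4)
  # and p-values spread over the unit interval rather than piling up
  expect_gt(mean(ps > 0.5), 0.2)
})

test_that("strong heterogeneous linear noise is detected as niche", {
  bp <- test_blueprint(S = 30, n_steps = 300)
  ps <- sapply(1:5, function(k) {
    ser <- simulate_community(bp, seed = 70 + k)
    neutral_covariance_test(ser, n_partitions = 40, n_null = 60,
                            seed = k)$p.value
  })
  expect_gte(mean(ps < 0.05), 0.6)
})

test_that("degenerate NCT inputs are rejected", {
  expect_error(neutral_covariance_test(
    series_from_matrix(matrix(runif(20), 10, 2))), "3 species")
  expect_error(neutral_covariance_test(
    series_from_matrix(matrix(runif(15), 5, 3))), "10 time")
  # a constant composition has no increments to test
  expect_error(neutral_covariance_test(
    series_from_matrix(matrix(1, 30, 4))), "degenerate")
})

test_that("neutrality_measures bundles both tests", {
  bp <- test_blueprint(S = 10, n_steps = 150)
  out <- neutrality_measures(simulate_community(bp, seed = 1),
                             n_partitions = 30, n_null = 40, seed = 2)
  expect_named(out, c("kl_divergence", "nct_p", "nct_label"))
  expect_gte(out$kl_divergence, 0)
  expect_true(out$nct_p >= 0 && out$nct_p <= 1)
  expect_true(out$nct_label %in% c("niche", "neutral"))
})
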