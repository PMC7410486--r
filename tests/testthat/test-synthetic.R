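test_that("community generation is reproducible and honours the blueprint", {
  bp <- test_blueprint(S = 40)
  a <- generate_community(bp, seed = 12)
  b <- generate_community(bp, seed = 12)
  expect_identical(a$params$interactions, b$params$interactions)
  expect_identical(a$x_star, b$x_star)

  # imposed growth: logistic communities satisfy g = |w_ii| x* exactly
  expect_equal(a$params$growth, -diag(a$params$interactions) * a$x_star,
               ignore_attr = TRUE)

  # equal-abundance blueprint: all species share x*
  bp_eq <- community_blueprint(S = 10, x_star_log10_sd = 0, n_steps = 50)
  eq <- generate_community(bp_eq, seed = 1)
  expect_equal(unname(eq$x_star), rep(100, 10))

  # heavy tail: lognormal steady states span at least four decades
  big <- generate_community(community_blueprint(S = 100), seed = 3)
  expect_gte(log10(max(big$x_star) / min(big$x_star)), 4)

  # growth mode keeps g dt inside the stated band and the derived
  # self-interactions span several decades
  gdt <- big$params$growth * 1
  expect_true(all(gdt >= 10^-0.5 - 1e-9 & gdt <= 10^1.5 + 1e-9))
  expect_gte(diff(range(log10(-diag(big$params$interactions)))), 3)
})

test_that("interacting draws are rejected until stable", {
  bp <- test_blueprint(S = 8, alpha = 0.02)
  com <- generate_community(bp, seed = 5)
  expect_true(linear_stability(com$params, com$x_star)$stable)
})

test_that("the color calibration curve is monotone between the OU limits", {
  cal <- calibrate_color_curve(seq(-1, 2, by = 0.5), n_rep = 4,
                               n_steps = 600, seed = 21)
  tbl <- tidy(cal)
  expect_true(all(diff(tbl$fitted_slope) >= 0))
  expect_lt(tbl$fitted_slope[1], -1)    # toward brown at slow relaxation
  expect_gt(tbl$fitted_slope[nrow(tbl)], -0.3)  # white at fast relaxation
})

test_that("self-interaction inference is self-consistent at calibration points", {
  cal <- calibrate_color_curve(seq(-1.5, 0.75, by = 0.25), n_rep = 5,
                               n_steps = 1000, seed = 22)
  # species generated at a mid-grid point with the calibration's own
  # blueprint are recovered within the grid dispersion
  g <- rep(10^-0.5, 12)
  ser <- simulate_glv(logistic_params(g), noise_spec(sigma_lin = 0.1),
                      t_max = 1000, delta_t = 1, seed = 23)
  est <- infer_self_interactions(noise_color(ser), cal)
  ok <- est$in_range
  expect_gt(sum(ok), 6)
  tol <- 3 * max(tidy(cal)$sd_slope) /
    0.5  # dispersion mapped through a typical pink-band gradient
  expect_lt(abs(median(est$log10_gdt[ok]) - (-0.5)), tol)
  # uncertainty inflates where the curve is flat (white end vs pink band)
  tbl <- tidy(cal)
  se_fun <- function(lgdt) {
    g2 <- rep(10^lgdt, 12)
    s2 <- simulate_glv(logistic_params(g2), noise_spec(sigma_lin = 0.1),
                       t_max = 1000, delta_t = 1, seed = 24)
    e2 <- infer_self_interactions(noise_color(s2), cal)
    median(e2$log10_self_se, na.rm = TRUE)
  }
  expect_gt(se_fun(0.6), se_fun(-0.5))
})

test_that("noise-mix scans interpolate between the channel signatures", {
  bp <- test_blueprint(S = 25, n_steps = 300)
  scan <- scan_noise_mix(bp, sigma_lin_grid = c(0, 1.5),
                         sigma_sqrt_grid = c(0, 7), n_rep = 2, seed = 31)
  scan <- scan[!(scan$sigma_lin == 0 & scan$sigma_sqrt == 0), ]
  agg <- dplyr::summarise(dplyr::group_by(scan, sigma_lin, sigma_sqrt),
                          slope = mean(slope), .groups = "drop")
  lin <- agg$slope[agg$sigma_lin > 0 & agg$sigma_sqrt == 0]
  sqr <- agg$slope[agg$sigma_lin == 0 & agg$sigma_sqrt > 0]
  mix <- agg$slope[agg$sigma_lin > 0 & agg$sigma_sqrt > 0]
  expect_gt(lin, 0.85)
  expect_lt(sqr, lin)
  expect_true(mix >= sqr - 0.1 && mix <= lin + 0.1)
})

test_that("ratio-width scans grow with the noise strength", {
  bp <- test_blueprint(S = 20, n_steps = 300)
  scan <- scan_ratio_width(bp, sigma_grid = c(0.2, 0.8, 2), n_rep = 2,
                           seed = 41)
  agg <- tapply(scan$median_width, scan$sigma_lin, mean)
  expect_true(all(diff(agg) > 0))
})

test_that("a community study bundles all characteristics", {
  bp <- test_blueprint(S = 15, n_steps = 200)
  st <- run_community_study(bp, n_rep = 3, n_partitions = 30, n_null = 40,
                            seed = 51)
  expect_equal(nrow(st$replicates), 3)
  expect_named(st$replicates, c("replicate", "seed", "slope", "median_width",
                                "median_ks_p", "kl_divergence", "nct_p"))
  expect_true(all(st$replicates$nct_p >= 0 & st$replicates$nct_p <= 1))
  expect_true(st$niche_fraction >= 0 && st$niche_fraction <= 1)
  g <- glance(st)
  expect_equal(g$n_rep, 3)
  expect_equal(tidy(st), st$replicates)
})
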