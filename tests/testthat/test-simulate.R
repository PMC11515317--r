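test_that("panels have the contracted shape: balanced, x constant per subject", {
  p <- simulate_mixed(mixed_spec(), n = 4, n_waves = 2, seed = 1)
  expect_equal(nrow(p), 8)
  expect_equal(as.integer(table(p$id)), rep(2L, 4))
  expect_true(all(tapply(p$x, p$id, function(v) length(unique(v))) == 1))
  expect_s3_class(validate_panel(p), "tbl_df")

  pl <- simulate_lgm(lgm_spec(), n = 7, seed = 2)
  expect_equal(nrow(pl), 35) # T = 5 under the default loadings
  expect_equal(as.integer(table(pl$wave)), rep(7L, 5))
})

test_that("same seed and configuration reproduce the panel bit for bit", {
  a <- simulate_mixed(mixed_spec(), n = 30, n_waves = 3, seed = 99)
  b <- simulate_mixed(mixed_spec(), n = 30, n_waves = 3, seed = 99)
  expect_identical(a, b)
  c1 <- simulate_lgm(lgm_spec(), n = 30, seed = 99, confounded = TRUE)
  c2 <- simulate_lgm(lgm_spec(), n = 30, seed = 99, confounded = TRUE)
  expect_identical(c1, c2)
})

test_that("with all noise removed the mixed panel equals the deterministic
           recursion of the generating equations", {
  sp <- mixed_spec(beta_x = 0, phi = matrix(0, 4, 4),
                   sigma_eps_m = 0, sigma_eps_y = 0)
  p <- simulate_mixed(sp, n = 3, n_waves = 4, seed = 5)
  # hand recursion (wave 1 has no lagged terms)
  m <- y <- numeric(4)
  for (t in 1:4) {
    m[t] <- sp$beta0 +
      (if (t > 1) sp$beta_lag_m * m[t - 1] + sp$beta_lag_y * y[t - 1] else 0)
    y[t] <- sp$gamma0 + sp$gamma_x * p$x[p$wave == t][1] + sp$gamma_m * m[t] +
      (if (t > 1) sp$gamma_lag_m * m[t - 1] + sp$gamma_lag_y * y[t - 1] else 0)
  }
  one <- p[p$id == 1, ]
  expect_equal(one$m, m, tolerance = 1e-12)
  expect_equal(one$y, y, tolerance = 1e-12)
})

test_that("with all noise removed and X = 0 the latent growth outcome equals
           the composed path means", {
  sp <- lgm_spec(zeta_sd = 0, eps_sd_m = 0, eps_sd_y = 0)
  p <- simulate_lgm(sp, n = 40, seed = 6)
  p0 <- p[p$x == 0, ]
  expected <- sp$gamma00 + sp$lambda[p0$wave] *
    (sp$gamma10 + sp$gamma12 * sp$beta00 + sp$gamma13 * sp$beta10)
  expect_equal(p0$y, expected, tolerance = 1e-12)
  # wave-1 outcome mean does not involve the mediator latents
  expect_equal(unique(p0$y[p0$wave == 1]), sp$gamma00)
})

test_that("large-sample moments match the generating equations", {
  # E[M_1 | X = 1] = beta0 + beta_x = 1.8 under the reference design
  p <- simulate_mixed(mixed_spec(), n = 2e5, n_waves = 2, seed = 7)
  expect_equal(mean(p$m[p$wave == 1 & p$x == 1]), 1.8, tolerance = 0.02)
  # exposure is randomised fairly
  x <- p$x[p$wave == 1]
  expect_equal(mean(x), 0.5, tolerance = 3 * sqrt(0.25 / length(x)))

  # mean trajectory of a random mixed spec follows the mean recursion;
  # the Y -> M feedback is switched off because with beta_lag_y != 0 the
  # mediator inherits the outcome's random slopes and the plain recursion
  # stops being the exact mean (the covariance terms are what the
  # Monte-Carlo effect oracle exists for)
  sp <- rand_mixed_spec(11)
  sp$beta_lag_y <- 0
  q <- simulate_mixed(sp, n = 1e5, n_waves = 3, seed = 8)
  for (xv in 0:1) {
    em <- ey <- numeric(3)
    for (t in 1:3) {
      em[t] <- sp$beta0 + sp$beta_x * xv +
        (if (t > 1) sp$beta_lag_m * em[t - 1] + sp$beta_lag_y * ey[t - 1] else 0)
      ey[t] <- sp$gamma0 + sp$gamma_x * xv + sp$gamma_m * em[t] +
        (if (t > 1) sp$gamma_lag_m * em[t - 1] + sp$gamma_lag_y * ey[t - 1] else 0)
    }
    sub <- q[q$x == xv, ]
    got_m <- as.numeric(tapply(sub$m, sub$wave, mean))
    got_y <- as.numeric(tapply(sub$y, sub$wave, mean))
    n_g <- sum(sub$wave == 1)
    mc <- 3 * max(as.numeric(tapply(sub$y, sub$wave, sd))) / sqrt(n_g)
    expect_lt(max(abs(got_m - em)), mc)
    expect_lt(max(abs(got_y - ey)), mc)
  }

  # LGM: slope of M on lambda among X = 1 estimates beta10 + beta11 = 1.17
  pl <- simulate_lgm(lgm_spec(), n = 5e4, seed = 9)
  w <- tidyr::pivot_wider(pl, id_cols = c("id", "x"), names_from = "wave",
                          values_from = c("m", "y"), names_sep = "")
  lam <- 0:4
  mm <- as.matrix(w[w$x == 1, paste0("m", 1:5)])
  slopes <- (mm %*% (lam - mean(lam))) / sum((lam - mean(lam))^2)
  expect_equal(mean(slopes), 1.17, tolerance = 3 * sd(slopes) / sqrt(nrow(mm)))

  # LGM empirical covariance matches the model-implied covariance
  z <- as.matrix(w[w$x == 1, c(paste0("m", 1:5), paste0("y", 1:5))])
  implied <- sepmed:::lgm_implied_moments(unclass(lgm_spec()), x = 1)
  expect_equal(unname(cov(z)), unname(implied$sigma), tolerance = 0.06)
  expect_equal(unname(colMeans(z)), unname(implied$mu), tolerance = 0.05)
})

test_that("the wave-1 confounder adds covariance between M1 and Y1 only", {
  n <- 6e4
  pu <- simulate_mixed(mixed_spec(), n = n, n_waves = 2, seed = 10,
                       confounded = TRUE, u_effect = 1, u_sd = 1)
  p0 <- simulate_mixed(mixed_spec(), n = n, n_waves = 2, seed = 10)
  cv <- function(p, t) {
    sub <- p[p$wave == t & p$x == 0, ]
    cov(sub$m, sub$y)
  }
  # Cov(M1, Y1) gains ~ u_effect^2 * u_sd^2 * (1 + gamma_m); later-wave
  # residual structure is only affected through the propagated wave-1 shock
  expect_gt(cv(pu, 1) - cv(p0, 1), 0.5)
})
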