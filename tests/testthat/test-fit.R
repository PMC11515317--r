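test_that("an exposure-free Bernoulli mediator is fitted at its sample mean", {
  # one wave, half the mediator values 1 within each exposure arm
  panel <- tibble::tibble(
    id = 1:16, wave = 1L,
    x = rep(c(0, 1), each = 8),
    m = rep(c(0, 1), 8),
    y = rnorm(16))
  fit <- fit_glm_sequence(panel, family_m = "binomial-logit")
  b <- fit$med[[1]]$coef
  expect_equal(unname(plogis(b[["(Intercept)"]])), 0.5, tolerance = 1e-6)
  expect_equal(unname(b[["x"]]), 0, tolerance = 1e-6)
})

test_that("the pooled GLM sequence recovers the generating coefficients when
           the random effects vanish", {
  sp0 <- mixed_spec(phi = matrix(0, 4, 4))
  panel <- simulate_mixed(sp0, n = 5000, n_waves = 5, seed = 21)
  fit <- fit_glm_sequence(panel)
  cf <- fit$med[[2]]$coef
  # the fast least-squares path must agree with the reference fitter ...
  df <- sepmed:::add_lags(validate_panel(panel), 1L)
  ref <- lm(m ~ x + m_lag1 + y_lag1, data = df)
  expect_equal(unname(cf), unname(coef(ref)), tolerance = 1e-10)
  # ... and recover beta_x within 3 standard errors of 0.5
  se_bx <- summary(ref)$coefficients["x", "Std. Error"]
  expect_lt(abs(cf[["x"]] - 0.5), 3 * se_bx)
  # gaussian residual scale is the residual mean squared error
  expect_equal(fit$med[[2]]$sigma, summary(ref)$sigma, tolerance = 1e-10)
})

test_that("gamma-log outcome families keep fitted means positive", {
  sp <- mixed_spec(gamma0 = 0.2, gamma_x = 0.3, gamma_m = 0.1,
                   gamma_lag_m = 0.05, gamma_lag_y = 0.05,
                   beta_lag_y = 0.05, phi = matrix(0, 4, 4),
                   sigma_eps_y = 0.3, family_y = "gamma-log")
  panel <- simulate_mixed(sp, n = 800, n_waves = 3, seed = 22)
  expect_true(all(panel$y > 0))
  fit <- fit_glm_sequence(panel, family_y = "gamma-log")
  mu <- suppressWarnings(
    gformula_mean(fit, intervention(1, 0), S = 3000, seed = 23))
  expect_true(all(mu$mean > 0))
})

test_that("the mixed fit recovers the reference design within 3 SEs at n = 5000", {
  panel <- simulate_mixed(mixed_spec(), n = 5000, n_waves = 5, seed = 24)
  fit <- suppressWarnings(suppressMessages(fit_mixed(panel)))
  truth_m <- c("(Intercept)" = 1.3, x = 0.5, m_lag1 = 0.27, y_lag1 = 0.11)
  truth_y <- c("(Intercept)" = 0.45, x = 0.7, m = 0.2, m_lag1 = 0.08,
               y_lag1 = 0.34)
  sm <- summary(fit$fits$mediator)$coefficients
  sy <- summary(fit$fits$outcome)$coefficients
  expect_true(all(abs(sm[names(truth_m), "Estimate"] - truth_m) <
                    3 * sm[names(truth_m), "Std. Error"]))
  expect_true(all(abs(sy[names(truth_y), "Estimate"] - truth_y) <
                    3 * sy[names(truth_y), "Std. Error"]))
  # random-slope variance near its identity-covariance value
  # ([0.8, 1.2] is a +/- 3 empirical-SE band measured across pilot replicates)
  expect_gt(fit$estimates$phi["gM", "gM"], 0.8)
  expect_lt(fit$estimates$phi["gM", "gM"], 1.2)
  expect_equal(fit$estimates$sigma_eps_m, 1, tolerance = 0.05)
})

test_that("degenerate noise is handled: tiny noise recovers the coefficients,
           zero noise raises the collinearity error", {
  sp <- mixed_spec(phi = matrix(0, 4, 4), sigma_eps_m = 0.05,
                   sigma_eps_y = 0.05)
  panel <- simulate_mixed(sp, n = 2000, n_waves = 4, seed = 25)
  fit <- fit_glm_sequence(panel)
  expect_lt(abs(fit$med[[2]]$coef[["x"]] - 0.5), 0.02)
  expect_lt(abs(fit$out[[2]]$coef[["m"]] - 0.2), 0.02)
  expect_lt(abs(fit$out[[2]]$coef[["y_lag1"]] - 0.34), 0.02)
  # with zero noise the lagged design is deterministic in (x, wave): the
  # coefficients are unidentified and the fitter must say so, not guess
  sp0 <- mixed_spec(phi = matrix(0, 4, 4), sigma_eps_m = 0, sigma_eps_y = 0)
  p0 <- simulate_mixed(sp0, n = 50, n_waves = 4, seed = 26)
  expect_error(fit_glm_sequence(p0), "non-finite|collinear")
})

test_that("the latent growth ML fit recovers the reference design within 3 SEs", {
  panel <- simulate_lgm(lgm_spec(), n = 5000, seed = 26)
  fit <- fit_lgm(panel, se = TRUE)
  expect_equal(fit$convergence$code, 0)
  truth <- c(beta00 = 0.21, beta01 = 0.16, beta10 = 0.7, beta11 = 0.47,
             gamma00 = 0.3, gamma01 = 0.14, gamma10 = 0.59, gamma11 = 0.27,
             gamma12 = 0.44, gamma13 = 0.19)
  est <- unlist(fit$estimates[names(truth)])
  expect_true(all(abs(est - truth) < 3 * fit$se[names(truth)]),
              label = "all structural coefficients within 3 SEs")
  # implied moments at the optimum track the sample moments
  stats <- sepmed:::lgm_group_stats(panel)
  for (i in 1:2) {
    expect_equal(unname(fit$implied[[i]]$mu), unname(stats[[i]]$mean),
                 tolerance = 0.05)
    expect_equal(unname(fit$implied[[i]]$sigma), unname(stats[[i]]$cov),
                 tolerance = 0.15)
  }
})

test_that("exact-measurement latent growth data reproduce the two-stage
           oracle and recover the design", {
  sp <- lgm_spec(eps_sd_m = 0, eps_sd_y = 0)
  panel <- simulate_lgm(sp, n = 2000, seed = 27)
  fit <- fit_lgm(panel)
  expect_true(fit$convergence$degenerate)
  # with exact measurement the factor scores equal the true latents, so the
  # structural OLS in the test is an independent oracle for the estimates
  w <- tidyr::pivot_wider(panel, id_cols = c("id", "x"), names_from = "wave",
                          values_from = c("m", "y"), names_sep = "")
  A <- cbind(1, 0:4)
  eta_m <- as.matrix(w[paste0("m", 1:5)]) %*% A %*% solve(crossprod(A))
  eta_y <- as.matrix(w[paste0("y", 1:5)]) %*% A %*% solve(crossprod(A))
  oracle <- coef(lm(eta_y[, 2] ~ w$x + eta_m[, 1] + eta_m[, 2]))
  expect_equal(fit$estimates$gamma11, unname(oracle[2]), tolerance = 1e-8)
  expect_equal(fit$estimates$gamma12, unname(oracle[3]), tolerance = 1e-8)
  expect_equal(fit$estimates$gamma13, unname(oracle[4]), tolerance = 1e-8)
  expect_equal(fit$estimates$gamma12, 0.44, tolerance = 0.1)
})

test_that("omitting the mediator intercept from the slope equation shifts the
           exposure coefficient by the omitted-variable term", {
  panel <- simulate_lgm(lgm_spec(), n = 20000, seed = 28)
  fit <- fit_lgm(panel, omit_eta0m = TRUE)
  expect_equal(fit$estimates$gamma12, 0)
  # probability limits: gamma11 -> gamma11 + gamma12 * beta01 = 0.3404,
  # gamma13 unchanged at 0.19 (the freed disturbance covariance absorbs the
  # dropped path), psi14 -> gamma12 * var(zeta_0M) = 0.44
  expect_equal(fit$estimates$gamma11, 0.3404, tolerance = 0.02)
  expect_equal(fit$estimates$gamma13, 0.19, tolerance = 0.02)
  expect_equal(fit$estimates$psi14, 0.44, tolerance = 0.06)
})

test_that("fits are invariant to subject order", {
  panel <- simulate_mixed(mixed_spec(phi = matrix(0, 4, 4)), n = 400,
                          n_waves = 3, seed = 29)
  perm <- panel[order(rev(panel$id), panel$wave), ]
  f1 <- fit_glm_sequence(panel)
  f2 <- fit_glm_sequence(perm)
  expect_equal(f1$med[[2]]$coef, f2$med[[2]]$coef, tolerance = 1e-9)
  pl <- simulate_lgm(lgm_spec(), n = 300, seed = 30)
  pperm <- pl[order(rev(pl$id), pl$wave), ]
  g1 <- fit_lgm(pl)
  g2 <- fit_lgm(pperm)
  expect_equal(g1$estimates$gamma12, g2$estimates$gamma12, tolerance = 1e-6)
})
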