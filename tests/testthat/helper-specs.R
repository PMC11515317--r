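# Random but stable (seeded) mechanism specifications for property tests.
# Lag coefficients stay small so the cross-lagged recursion is stable over
# five waves.

rand_mixed_spec <- function(seed) {
  withr::with_seed(seed, {
    mixed_spec(
      beta0 = runif(1, -1, 2), beta_x = runif(1, 0.2, 0.8),
      beta_lag_m = runif(1, -0.3, 0.3), beta_lag_y = runif(1, -0.2, 0.2),
      gamma0 = runif(1, -1, 2), gamma_x = runif(1, 0.2, 0.8),
      gamma_m = runif(1, -0.3, 0.3), gamma_lag_m = runif(1, -0.2, 0.2),
      gamma_lag_y = runif(1, -0.3, 0.3),
      phi = diag(runif(4, 0.2, 1)),
      sigma_eps_m = runif(1, 0.5, 1.2), sigma_eps_y = runif(1, 0.5, 1.2))
  })
}

rand_lgm_spec <- function(seed) {
  withr::with_seed(seed, {
    lgm_spec(
      beta00 = runif(1, -0.5, 0.5), beta01 = runif(1, -0.5, 0.5),
      beta10 = runif(1, -0.5, 1), beta11 = runif(1, -0.5, 0.5),
      gamma00 = runif(1, -0.5, 0.5), gamma01 = runif(1, -0.5, 0.5),
      gamma10 = runif(1, -0.5, 1), gamma11 = runif(1, -0.5, 0.5),
      gamma12 = runif(1, -0.5, 0.5), gamma13 = runif(1, -0.5, 0.5),
      zeta_sd = runif(4, 0.5, 1.2),
      eps_sd_m = runif(1, 0.5, 1.2), eps_sd_y = runif(1, 0.5, 1.2))
  })
}

# Hand-built one-wave GLM sequence: mediator ~ Bernoulli(0.5) ignoring the
# exposure, outcome conditional mean identically equal to the mediator.
toy_seq_models <- function() {
  structure(
    list(
      med = list(list(coef = c("(Intercept)" = 0, x = 0), sigma = 1,
                      family = "binomial-logit")),
      out = list(list(coef = c("(Intercept)" = 0, x = 0, m = 1), sigma = 0,
                      family = "gaussian-identity")),
      n_waves = 1L, lag_order = 1L, pool = FALSE,
      family_m = "binomial-logit", family_y = "gaussian-identity"),
    class = "sepmed_seq")
}
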