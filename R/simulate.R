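# Forward-simulation engines shared by the data generators, the asymptotic
# truth oracles and the g-formula estimator. Each engine takes the exposure
# split into its two components: mediator equations see x_m, outcome
# equations see x_y. Passing the same vector for both reproduces ordinary
# data generation (Property P1). Pre-drawn noise can be supplied so that
# contrasts between interventions share common random numbers.

draw_mixed_noise <- function(n, n_waves, confounded = FALSE) {
  list(z_re = matrix(rnorm(n * 4), n, 4),
       em = matrix(rnorm(n * n_waves), n, n_waves),
       ey = matrix(rnorm(n * n_waves), n, n_waves),
       u = if (confounded) rnorm(n) else NULL)
}

inv_link <- function(pred, family) {
  switch(family,
    "gaussian-identity" = pred,
    "binomial-logit" = plogis(pred),
    "gamma-log" = exp(pred))
}

draw_response <- function(mu, sigma, family, z) {
  # z: standard-normal draws, consumed only by the gaussian family so that
  # common random numbers stay aligned across interventions for that family.
  switch(family,
    "gaussian-identity" = mu + sigma * z,
    "binomial-logit" = rbinom(length(mu), 1, mu),
    "gamma-log" = {
      shape <- 1 / sigma^2
      rgamma(length(mu), shape = shape, scale = mu / shape)
    })
}

# Returns M, Y (n x T) and ymean: E[Y_t | history, random effects], the
# conditional-mean surface used by the oracles and by the g-formula's
# final-wave averaging.
sim_mixed_engine <- function(spec, x_m, x_y, n_waves, noise,
                             u_effect = 0, u_sd = 1) {
  n <- length(x_m)
  ch <- chol_psd(spec$phi)
  u <- noise$z_re %*% ch # columns: b0, g0, gM, g_lag_m
  b0 <- u[, 1]; g0 <- u[, 2]; gM <- u[, 3]; gLM <- u[, 4]
  # u_effect recycles to (mediator path, outcome path); opposite signs give a
  # masking confounder
  u_effect <- rep_len(u_effect, 2)
  conf_m <- if (!is.null(noise$u)) u_effect[1] * u_sd * noise$u else 0
  conf_y <- if (!is.null(noise$u)) u_effect[2] * u_sd * noise$u else 0
  M <- Y <- ymean <- matrix(NA_real_, n, n_waves)
  for (t in seq_len(n_waves)) {
    pm <- spec$beta0 + b0 + spec$beta_x * x_m
    if (t > 1)
      pm <- pm + spec$beta_lag_m * M[, t - 1] + spec$beta_lag_y * Y[, t - 1]
    if (t == 1) pm <- pm + conf_m
    M[, t] <- draw_response(inv_link(pm, spec$family_m), spec$sigma_eps_m,
                            spec$family_m, noise$em[, t])
    py <- spec$gamma0 + g0 + spec$gamma_x * x_y + (spec$gamma_m + gM) * M[, t]
    if (t > 1)
      py <- py + (spec$gamma_lag_m + gLM) * M[, t - 1] +
        spec$gamma_lag_y * Y[, t - 1]
    if (t == 1) py <- py + conf_y
    ymean[, t] <- inv_link(py, spec$family_y)
    Y[, t] <- draw_response(ymean[, t], spec$sigma_eps_y, spec$family_y,
                            noise$ey[, t])
  }
  list(M = M, Y = Y, ymean = ymean)
}

chol_psd <- function(phi) {
  # Cholesky tolerant of semi-definite matrices (zero-variance components).
  ch <- tryCatch(chol(phi), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen((phi + t(phi)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(ev) * t(e$vectors)))
}

draw_lgm_noise <- function(n, n_waves, confounded = FALSE) {
  list(z_zeta = matrix(rnorm(n * 4), n, 4),
       em = matrix(rnorm(n * n_waves), n, n_waves),
       ey = matrix(rnorm(n * n_waves), n, n_waves),
       u = if (confounded) rnorm(n) else NULL)
}

sim_lgm_engine <- function(spec, x_m, x_y, noise, u_effect = 0, u_sd = 1) {
  n <- length(x_m)
  lam <- spec$lambda
  n_waves <- length(lam)
  zs <- spec$zeta_sd
  u_effect <- rep_len(u_effect, 2)
  conf <- if (!is.null(noise$u)) u_sd * noise$u else 0
  eta0m <- spec$beta00 + spec$beta01 * x_m + zs[1] * noise$z_zeta[, 1] +
    u_effect[1] * conf
  eta1m <- spec$beta10 + spec$beta11 * x_m + zs[2] * noise$z_zeta[, 2]
  eta0y <- spec$gamma00 + spec$gamma01 * x_y + zs[3] * noise$z_zeta[, 3]
  eta1y <- spec$gamma10 + spec$gamma11 * x_y + spec$gamma12 * eta0m +
    spec$gamma13 * eta1m + zs[4] * noise$z_zeta[, 4]
  M <- Y <- ymean <- matrix(NA_real_, n, n_waves)
  for (t in seq_len(n_waves)) {
    M[, t] <- eta0m + lam[t] * eta1m + spec$eps_sd_m * noise$em[, t]
    ymean[, t] <- eta0y + lam[t] * eta1y + u_effect[2] * conf
    Y[, t] <- ymean[, t] + spec$eps_sd_y * noise$ey[, t]
  }
  list(M = M, Y = Y, ymean = ymean)
}

panel_from_matrices <- function(x, M, Y) {
  n <- length(x)
  n_waves <- ncol(M)
  tibble::tibble(
    id = rep(seq_len(n), each = n_waves),
    wave = rep(seq_len(n_waves), times = n),
    x = rep(x, each = n_waves),
    m = as.vector(t(M)),
    y = as.vector(t(Y))
  )
}

#' Simulate a balanced panel from the mixed-effect mediation mechanism
#'
#' Generates `n` subjects observed at waves `1:n_waves`. The baseline
#' exposure is randomised, `X ~ Bernoulli(0.5)`; random effects are drawn
#' from `MVN(0, phi)`; mediator and outcome follow the cross-lagged equations
#' of [mixed_spec()] generated forward in wave order, wave-1 equations
#' omitting the lagged terms. With `confounded = TRUE`, a subject-level
#' unobserved confounder `U ~ Normal(0, u_sd)` is added (times `u_effect`) to
#' both the wave-1 mediator and wave-1 outcome linear predictors only,
#' violating assumption A1.
#'
#' @param spec A [mixed_spec()].
#' @param n Number of subjects (>= 2).
#' @param n_waves Number of waves T (>= 2).
#' @param seed Integer seed; required for reproducibility.
#' @param confounded Add the unobserved wave-1 confounder?
#' @param u_effect,u_sd Confounder path coefficient(s) and scale. `u_effect`
#'   recycles to length 2, `(mediator path, outcome path)`; opposite signs
#'   give a masking confounder that attenuates the apparent
#'   mediator-outcome association.
#' @return A tibble with columns `id, wave, x, m, y` (one row per
#'   subject-wave, balanced, `x` constant within subject).
#' @examples
#' panel <- simulate_mixed(mixed_spec(), n = 50, n_waves = 3, seed = 1)
#' @export
simulate_mixed <- function(spec, n, n_waves = 5, seed = NULL,
                           confounded = FALSE, u_effect = 1, u_sd = 1) {
  assert_valid_spec(spec)
  stopifnot(n >= 2, n_waves >= 2)
  run <- function() {
    x <- rbinom(n, 1, 0.5)
    noise <- draw_mixed_noise(n, n_waves, confounded)
    sim <- sim_mixed_engine(spec, x_m = x, x_y = x, n_waves = n_waves,
                            noise = noise, u_effect = u_effect, u_sd = u_sd)
    panel_from_matrices(x, sim$M, sim$Y)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Simulate a balanced panel from the latent growth mediation mechanism
#'
#' Generates `n` subjects with trajectories driven by latent intercepts and
#' slopes per [lgm_spec()]: exposure `X ~ Bernoulli(0.5)`, latent factors
#' drawn in topological order (mediator intercept and slope, outcome
#' intercept, then outcome slope given the mediator factors), observations
#' with independent Gaussian measurement error. With `confounded = TRUE`, a
#' subject-level `U ~ Normal(0, u_sd)` enters the mediator latent-intercept
#' equation and every outcome measurement equation with coefficient
#' `u_effect`, violating the outcome-side identifying assumption.
#'
#' @inheritParams simulate_mixed
#' @param spec An [lgm_spec()]; the number of waves is `length(spec$lambda)`.
#' @return A tibble with columns `id, wave, x, m, y`.
#' @examples
#' panel <- simulate_lgm(lgm_spec(), n = 50, seed = 1)
#' @export
simulate_lgm <- function(spec, n, seed = NULL, confounded = FALSE,
                         u_effect = 1, u_sd = 1) {
  assert_valid_spec(spec)
  stopifnot(n >= 2)
  n_waves <- length(spec$lambda)
  run <- function() {
    x <- rbinom(n, 1, 0.5)
    noise <- draw_lgm_noise(n, n_waves, confounded)
    sim <- sim_lgm_engine(spec, x_m = x, x_y = x, noise = noise,
                          u_effect = u_effect, u_sd = u_sd)
    panel_from_matrices(x, sim$M, sim$Y)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Simulate a panel from either mechanism
#'
#' Dispatches to [simulate_mixed()] or [simulate_lgm()] on the class of
#' `spec`.
#'
#' @inheritParams simulate_mixed
#' @param ... Passed to the mechanism-specific generator.
#' @export
simulate_panel <- function(spec, n, seed = NULL, ...) {
  args <- list(...)
  if (inherits(spec, "mixed_spec")) {
    do.call(simulate_mixed, c(list(spec = spec, n = n, seed = seed), args))
  } else if (inherits(spec, "lgm_spec")) {
    # the latent growth design fixes T through its loadings
    args$n_waves <- NULL
    do.call(simulate_lgm, c(list(spec = spec, n = n, seed = seed), args))
  } else {
    abort("spec must be a mixed_spec or lgm_spec")
  }
}
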