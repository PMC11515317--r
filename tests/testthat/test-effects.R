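# Closed-form and Monte-Carlo oracles for the true separable effects.
# Frozen two-wave mixed values below were derived by path-tracing the
# generating recursion and integrating over the random effects:
#   SDE_2 = gamma_x (1 + beta_lag_y * gamma_m + gamma_lag_y)        = 0.9534
#   SIE_2 = beta_x (gamma_m + beta_lag_m gamma_m
#           + beta_lag_y (gamma_m^2 + Var(gM)) + gamma_lag_m
#           + gamma_m gamma_lag_y)                                   = 0.2582
# and are cross-checked against the Monte-Carlo oracle in the suite.

test_that("latent growth effects follow the loading-linear closed form", {
  sp <- lgm_spec()
  eff <- lgm_effects(sp, wave = 1:5)
  rate_sie <- sp$beta01 * sp$gamma12 + sp$beta11 * sp$gamma13
  expect_equal(eff$sde, sp$gamma01 + sp$gamma11 * (0:4))
  expect_equal(eff$sie, rate_sie * (0:4))
  expect_equal(eff$sie[1], 0) # lambda_1 = 0 annihilates the indirect paths
  # exactly linear in lambda for the SIE, affine for the SDE
  expect_equal(diff(eff$sie), rep(rate_sie, 4))
  expect_equal(diff(eff$sde), rep(sp$gamma11, 4))
})

test_that("effects are antisymmetric in the contrast and zero at the null", {
  sp <- lgm_spec()
  fwd <- lgm_effects(sp, 1:5, contrast = c(1, 0))
  rev <- lgm_effects(sp, 1:5, contrast = c(0, 1))
  expect_equal(fwd$sde, -rev$sde)
  expect_equal(fwd$sie, -rev$sie)
  null <- lgm_effects(sp, 1:5, contrast = c(1, 1))
  expect_true(all(null$sde == 0) && all(null$sie == 0))

  mx <- mixed_effects_closed(mixed_spec(), 1:2, contrast = c(1, 1))
  expect_true(all(mx$sde == 0) && all(mx$sie == 0))
})

test_that("two-wave mixed closed forms match the frozen derivation", {
  eff <- mixed_effects_closed(mixed_spec(), wave = 1:2)
  expect_equal(eff$sde, c(0.7, 0.9534), tolerance = 1e-12)
  expect_equal(eff$sie, c(0.1, 0.2582), tolerance = 1e-12)
  # without random-slope variance the second-moment correction vanishes
  flat <- mixed_effects_closed(mixed_spec(phi = matrix(0, 4, 4)), wave = 2)
  expect_equal(flat$sie, 0.2032, tolerance = 1e-12)
})

test_that("closed forms guard their preconditions", {
  expect_error(mixed_effects_closed(mixed_spec(), wave = 3), "waves 1 and 2")
  cross <- diag(4); cross[1, 3] <- cross[3, 1] <- 0.4
  expect_error(mixed_effects_closed(mixed_spec(phi = cross), wave = 1),
               "not identified")
  expect_error(mixed_effects_closed(mixed_spec(family_y = "gamma-log"), 1),
               "gaussian")
  expect_error(mixed_effects_asymptotic(mixed_spec(), 1, draws = 500),
               "1000")
  expect_error(lgm_effects(lgm_spec(), wave = 9), "out of range")
})

test_that("the Monte-Carlo oracle agrees with the closed forms at waves 1-2", {
  specs <- lapply(1:20, rand_mixed_spec)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    closed <- mixed_effects_closed(sp, wave = 1:2)
    mc <- mixed_effects_asymptotic(sp, wave = 1:2, draws = 2e4, seed = 100 + i)
    tol_sde <- 3 * pmax(mc$sde_se, 1e-9)
    tol_sie <- 3 * pmax(mc$sie_se, 1e-9)
    expect_true(all(abs(mc$sde - closed$sde) < tol_sde),
                label = sprintf("spec %d sde agreement", i))
    expect_true(all(abs(mc$sie - closed$sie) < tol_sie),
                label = sprintf("spec %d sie agreement", i))
  }
})

test_that("direct and indirect effects telescope to the total effect", {
  # mixed mechanism: Monte-Carlo, combined error budget
  for (i in 1:5) {
    sp <- rand_mixed_spec(200 + i)
    eff <- mixed_effects_asymptotic(sp, wave = 1:4, draws = 2e4,
                                    seed = 300 + i)
    tot <- total_effect(sp, wave = 1:4, draws = 2e4, seed = 400 + i)
    tol <- 3 * sqrt(eff$sde_se^2 + eff$sie_se^2 + tot$total_se^2) + 1e-8
    expect_true(all(abs(eff$sde + eff$sie - tot$total) < tol),
                label = sprintf("telescoping, mixed spec %d", i))
  }
  # latent growth mechanism: exact
  for (i in 1:5) {
    sp <- rand_lgm_spec(500 + i)
    eff <- lgm_effects(sp)
    tot <- total_effect(sp, wave = seq_along(sp$lambda))
    expect_equal(eff$sde + eff$sie, tot$total, tolerance = 1e-12)
  }
})

test_that("a spec with no open mediator-outcome path has zero indirect effect", {
  phi <- diag(c(1, 1, 0, 0)) # no random slopes on the mediator terms
  sp <- mixed_spec(gamma_m = 0, gamma_lag_m = 0, phi = phi)
  eff <- mixed_effects_asymptotic(sp, wave = 1:4, draws = 2e4, seed = 17)
  expect_true(all(abs(eff$sie) < 3 * pmax(eff$sie_se, 1e-9)))
})

test_that("the mixed Monte-Carlo oracle is reproducible and wave-consistent", {
  a <- mixed_effects_asymptotic(mixed_spec(), wave = 2, draws = 5000, seed = 3)
  b <- mixed_effects_asymptotic(mixed_spec(), wave = 2, draws = 5000, seed = 3)
  expect_identical(a, b)
})
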