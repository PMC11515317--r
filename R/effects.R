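# True separable effects implied by a mechanism specification: exact closed
# forms where the linear structure admits them, Monte-Carlo evaluation of the
# generating recursion elsewhere. These are the package's ground-truth
# oracles for the estimator and the simulation-study harness.
#
# Conventions, for a contrast c(x, xref):
#   SDE = E[Y_t(X^Y = x,    X^M = xref)] - E[Y_t(X^Y = xref, X^M = xref)]
#   SIE = E[Y_t(X^Y = x,    X^M = x   )] - E[Y_t(X^Y = x,    X^M = xref)]
# so SDE + SIE telescopes to the total effect E[Y_t(x)] - E[Y_t(xref)].

effects_tibble <- function(wave, sde, sie, contrast, ...) {
  out <- tibble::tibble(wave = as.integer(wave), sde = sde, sie = sie, ...)
  attr(out, "contrast") <- contrast
  class(out) <- c("sepmed_effects", class(out))
  out
}

check_contrast <- function(contrast) {
  if (length(contrast) != 2 || !all(contrast %in% c(0, 1)))
    abort("contrast must be two exposure levels in {0, 1}, c(x, xref)")
  as.numeric(contrast)
}

#' True separable effects of a latent growth mechanism (closed form)
#'
#' In the linear latent growth mechanism the separable effects at wave `t`
#' with loading \eqn{\lambda_t} are exact:
#' \deqn{SDE_t = (\gamma_{01} + \gamma_{11}\lambda_t)(x - x')}
#' \deqn{SIE_t = \lambda_t(\beta_{01}\gamma_{12} + \beta_{11}\gamma_{13})(x - x')}
#' The indirect effect is zero at any wave with \eqn{\lambda_t = 0} (under
#' the default coding, wave 1), because the mediator latents enter the
#' outcome only through the latent slope.
#'
#' @param spec An [lgm_spec()].
#' @param wave Integer wave(s) in `1:length(spec$lambda)`.
#' @param contrast `c(x, xref)`, the two exposure levels compared.
#' @return A `sepmed_effects` tibble with columns `wave`, `sde`, `sie`.
#' @examples
#' lgm_effects(lgm_spec(), wave = 1:5)
#' @export
lgm_effects <- function(spec, wave = seq_along(spec$lambda),
                        contrast = c(1, 0)) {
  assert_valid_spec(spec)
  contrast <- check_contrast(contrast)
  if (any(wave < 1 | wave > length(spec$lambda)))
    abort("wave out of range for this specification")
  d <- contrast[1] - contrast[2]
  lam <- spec$lambda[wave]
  effects_tibble(
    wave = wave,
    sde = (spec$gamma01 + spec$gamma11 * lam) * d,
    sie = lam * (spec$beta01 * spec$gamma12 + spec$beta11 * spec$gamma13) * d,
    contrast = contrast
  )
}

#' True separable effects of the mixed mechanism at waves 1-2 (closed form)
#'
#' Path-traces the cross-lagged generating recursion and integrates over the
#' random effects. At wave 1 only the contemporaneous paths are open:
#' \eqn{SDE_1 = \gamma_X (x - x')} and
#' \eqn{SIE_1 = \beta_X \gamma_M (x - x')}. At wave 2 the direct effect adds
#' the paths through \eqn{Y_1},
#' \deqn{SDE_2 = \gamma_X (1 + \beta_{\ell_1(Y)}\gamma_M +
#'   \gamma_{\ell_1(Y)})(x - x'),}
#' and the indirect effect sums the five open mediator paths; the path
#' \eqn{X^M \to M_1 \to Y_1 \to M_2 \to Y_2} carries the concurrent-mediator
#' coefficient twice, so integrating over the random slope contributes its
#' second moment \eqn{E[(\gamma_M + g_M)^2] = \gamma_M^2 + Var(g_M)}:
#' \deqn{SIE_2 = \beta_X [\gamma_M + \beta_{\ell_1(M)}\gamma_M +
#'   \beta_{\ell_1(Y)}(\gamma_M^2 + Var(g_M)) + \gamma_{\ell_1(M)} +
#'   \gamma_M \gamma_{\ell_1(Y)}](x - x').}
#' Covariances confined to the outcome random-effect block multiply terms
#' that are constant across interventions at these horizons and cancel from
#' the contrasts, so the formulas hold for any block-diagonal \eqn{\Phi}.
#' Requires Gaussian-identity families; for later waves use
#' [mixed_effects_asymptotic()].
#'
#' @param spec A [mixed_spec()] with diagonal or block-diagonal `phi`.
#' @param wave Integer wave(s) in `{1, 2}`.
#' @inheritParams lgm_effects
#' @return A `sepmed_effects` tibble.
#' @examples
#' mixed_effects_closed(mixed_spec(), wave = 1:2)
#' @export
mixed_effects_closed <- function(spec, wave = 1:2, contrast = c(1, 0)) {
  assert_valid_spec(spec)
  contrast <- check_contrast(contrast)
  if (any(!wave %in% 1:2))
    abort("closed forms are implemented for waves 1 and 2 only")
  if (spec$family_m != "gaussian-identity" ||
      spec$family_y != "gaussian-identity")
    abort("closed forms require gaussian-identity families")
  ident <- check_identifiability(spec)
  if (ident$status == "not_identified")
    abort(paste("separable effects are not identified:", ident$rationale))
  d <- contrast[1] - contrast[2]
  var_gm <- spec$phi["gM", "gM"]
  sde <- ifelse(wave == 1,
    spec$gamma_x * d,
    spec$gamma_x *
      (1 + spec$beta_lag_y * spec$gamma_m + spec$gamma_lag_y) * d)
  sie <- ifelse(wave == 1,
    spec$beta_x * spec$gamma_m * d,
    spec$beta_x * (spec$gamma_m +
                     spec$beta_lag_m * spec$gamma_m +
                     spec$beta_lag_y * (spec$gamma_m^2 + var_gm) +
                     spec$gamma_lag_m +
                     spec$gamma_m * spec$gamma_lag_y) * d)
  effects_tibble(wave = wave, sde = sde, sie = sie, contrast = contrast)
}

#' True separable effects of the mixed mechanism by Monte Carlo
#'
#' Evaluates the interventional means \eqn{E[Y_t(X^Y, X^M)]} by forward
#' simulation of the generating recursion with the exposure split into its
#' two components (mediator equations see \eqn{X^M}, outcome equations see
#' \eqn{X^Y}), averaging the outcome conditional mean over simulated
#' subjects. The three interventions share one set of random-effect and
#' noise draws (common random numbers), so the Monte-Carlo standard errors
#' reported are those of the paired contrasts. Works at any wave and with
#' any supported family.
#'
#' @param spec A [mixed_spec()].
#' @param wave Integer wave(s) in `1:n_waves`.
#' @param draws Number of simulated subjects (>= 1000; this is an oracle, a
#'   coarse evaluation would be misleading).
#' @param seed Integer seed for the simulation draws.
#' @param n_waves Number of waves to simulate; defaults to `max(wave)`.
#' @inheritParams lgm_effects
#' @return A `sepmed_effects` tibble with additional columns `sde_se`,
#'   `sie_se` (Monte-Carlo standard errors).
#' @examples
#' mixed_effects_asymptotic(mixed_spec(), wave = 2, draws = 5000, seed = 1)
#' @export
mixed_effects_asymptotic <- function(spec, wave, contrast = c(1, 0),
                                     draws = 1e4, seed = NULL,
                                     n_waves = max(wave)) {
  assert_valid_spec(spec)
  contrast <- check_contrast(contrast)
  if (draws < 1000) abort("draws must be at least 1000 for the oracle")
  if (any(wave < 1 | wave > n_waves)) abort("wave out of range")
  x <- contrast[1]; xref <- contrast[2]
  run <- function() {
    noise <- draw_mixed_noise(draws, n_waves)
    cm <- function(x_y, x_m) {
      sim_mixed_engine(spec, x_m = rep(x_m, draws), x_y = rep(x_y, draws),
                       n_waves = n_waves, noise = noise)$ymean
    }
    a <- cm(x, xref) # (X^Y = x,    X^M = xref)
    b <- cm(xref, xref) # reference world
    cc <- cm(x, x) # both components at x
    dd_sde <- a - b
    dd_sie <- cc - a
    effects_tibble(
      wave = wave,
      sde = colMeans(dd_sde)[wave],
      sie = colMeans(dd_sie)[wave],
      sde_se = apply(dd_sde, 2, sd)[wave] / sqrt(draws),
      sie_se = apply(dd_sie, 2, sd)[wave] / sqrt(draws),
      contrast = contrast
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Total effect of the exposure on the outcome at a wave
#'
#' The total effect \eqn{E[Y_t(X = x)] - E[Y_t(X = x')]} — by Property P1,
#' setting both exposure components to the same level is equivalent to
#' setting the exposure itself. Computed in closed form for the latent
#' growth mechanism (where it equals `sde + sie` exactly) and by forward
#' simulation with common random numbers for the mixed mechanism.
#'
#' @inheritParams mixed_effects_asymptotic
#' @param spec A [mixed_spec()] or [lgm_spec()].
#' @return A tibble with columns `wave`, `total` (and `total_se` for the
#'   Monte-Carlo path).
#' @export
total_effect <- function(spec, wave, contrast = c(1, 0), draws = 1e4,
                         seed = NULL) {
  assert_valid_spec(spec)
  contrast <- check_contrast(contrast)
  if (inherits(spec, "lgm_spec")) {
    eff <- lgm_effects(spec, wave, contrast)
    return(tibble::tibble(wave = eff$wave, total = eff$sde + eff$sie))
  }
  if (draws < 1000) abort("draws must be at least 1000 for the oracle")
  n_waves <- max(wave)
  x <- contrast[1]; xref <- contrast[2]
  run <- function() {
    noise <- draw_mixed_noise(draws, n_waves)
    cc <- sim_mixed_engine(spec, x_m = rep(x, draws), x_y = rep(x, draws),
                           n_waves = n_waves, noise = noise)$ymean
    b <- sim_mixed_engine(spec, x_m = rep(xref, draws),
                          x_y = rep(xref, draws),
                          n_waves = n_waves, noise = noise)$ymean
    dd <- cc - b
    tibble::tibble(wave = as.integer(wave),
                   total = colMeans(dd)[wave],
                   total_se = apply(dd, 2, sd)[wave] / sqrt(draws))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
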