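# Parametric mediational g-formula: Monte-Carlo evaluation of interventional
# outcome means under split exposure components, separable-effect contrasts,
# and cluster-bootstrap confidence intervals.

#' Specify an intervention on the two exposure components
#'
#' @param x_y Level assigned to the outcome component of the exposure.
#' @param x_m Level assigned to the mediator component.
#' @return A named list; setting `x_y == x_m == x` is equivalent to setting
#'   the exposure itself to `x` (Property P1).
#' @export
intervention <- function(x_y, x_m) {
  if (!all(c(x_y, x_m) %in% c(0, 1)))
    abort("intervention levels must be in {0, 1}")
  list(x_y = x_y, x_m = x_m)
}

# forward simulation through a fitted GLM sequence
sim_seq_engine <- function(models, x_m, x_y, noise) {
  s <- length(x_m)
  tt <- models$n_waves
  M <- Y <- ymean <- matrix(NA_real_, s, tt)
  lin_pred <- function(cf, xvec, t, m_cur = NULL) {
    pred <- rep(cf[["(Intercept)"]], s)
    if ("x" %in% names(cf)) pred <- pred + cf[["x"]] * xvec
    if (!is.null(m_cur) && "m" %in% names(cf)) pred <- pred + cf[["m"]] * m_cur
    for (nm in grep("^(m|y)_lag", names(cf), value = TRUE)) {
      k <- as.integer(sub("^[my]_lag", "", nm))
      if (t - k >= 1) {
        h <- if (startsWith(nm, "m")) M[, t - k] else Y[, t - k]
        pred <- pred + cf[[nm]] * h
      }
    }
    pred
  }
  for (t in seq_len(tt)) {
    mm <- models$med[[t]]
    mu_m <- inv_link(lin_pred(mm$coef, x_m, t), mm$family)
    M[, t] <- draw_response(mu_m, sqrt_scale(mm), mm$family, noise$zm[, t])
    om <- models$out[[t]]
    ymean[, t] <- inv_link(lin_pred(om$coef, x_y, t, m_cur = M[, t]),
                           om$family)
    Y[, t] <- draw_response(ymean[, t], sqrt_scale(om), om$family,
                            noise$zy[, t])
  }
  if (any(!is.finite(ymean)))
    abort("non-finite values in the simulated outcome means; check the fitted models")
  list(M = M, Y = Y, ymean = ymean)
}

sqrt_scale <- function(model) {
  # gaussian: residual SD; gamma: draw_response expects the dispersion's sqrt
  if (model$family == "gamma-log") sqrt(model$sigma) else model$sigma
}

gf_noise <- function(models, s, n_waves = NULL) {
  tt <- n_waves %||% gf_waves(models)
  if (inherits(models, c("mixed_spec", "sepmed_mixed"))) {
    draw_mixed_noise(s, tt)
  } else if (inherits(models, c("lgm_spec", "sepmed_lgm"))) {
    draw_lgm_noise(s, tt)
  } else {
    list(zm = matrix(rnorm(s * tt), s, tt), zy = matrix(rnorm(s * tt), s, tt))
  }
}

gf_waves <- function(models) {
  if (inherits(models, "sepmed_seq")) models$n_waves
  else if (inherits(models, "sepmed_mixed")) NA_integer_ # caller supplies
  else if (inherits(models, "mixed_spec")) NA_integer_
  else if (inherits(models, "sepmed_lgm")) length(models$estimates$lambda)
  else if (inherits(models, "lgm_spec")) length(models$lambda)
  else abort("unsupported model object for the g-formula")
}

gf_ymean <- function(models, x_y, x_m, s, noise, n_waves) {
  if (inherits(models, "sepmed_seq")) {
    sim_seq_engine(models, rep(x_m, s), rep(x_y, s), noise)$ymean
  } else if (inherits(models, c("mixed_spec", "sepmed_mixed"))) {
    spec <- if (inherits(models, "sepmed_mixed")) as_mixed_spec(models)
            else models
    sim_mixed_engine(spec, rep(x_m, s), rep(x_y, s), n_waves, noise)$ymean
  } else {
    spec <- if (inherits(models, "sepmed_lgm")) as_lgm_spec(models)
            else models
    sim_lgm_engine(spec, rep(x_m, s), rep(x_y, s), noise)$ymean
  }
}

#' Interventional outcome means by the mediational g-formula
#'
#' Simulates `S` subjects forward through fitted (or true) models with the
#' exposure components split: mediator laws are evaluated under `x_m`,
#' outcome laws under `x_y`. Intermediate mediators and outcomes are sampled
#' from the fitted laws; the wave-`t` interventional mean averages the
#' outcome conditional expectation over the simulated subjects. For the
#' mixed backend, random effects are drawn per simulated subject from the
#' (estimated) random-effect distribution; for the latent growth backend the
#' integral over the latent factors is evaluated by drawing mediator-side
#' latents under `x_m` and outcome-side latents under `x_y`.
#'
#' @param models A fitted backend (`sepmed_seq`, `sepmed_mixed`,
#'   `sepmed_lgm`) or a true specification ([mixed_spec()], [lgm_spec()]).
#' @param intervention An [intervention()] (or a list with `x_y`, `x_m`).
#' @param S Number of simulated subjects; values below 10,000 draw a warning
#'   (acceptable for quick checks, not for production estimates).
#' @param seed Integer seed.
#' @param n_waves Number of waves (required for mixed-model inputs, where the
#'   specification does not fix T).
#' @return A tibble with columns `wave` and `mean`.
#' @examples
#' gformula_mean(lgm_spec(), intervention(1, 0), S = 2000, seed = 1)
#' @export
gformula_mean <- function(models, intervention, S = 10000, seed = NULL,
                          n_waves = NULL) {
  if (S < 1) abort("S must be positive")
  if (S < 10000)
    warn("S below 10,000: Monte-Carlo error may dominate; use S >= 10,000 for production runs")
  n_waves <- n_waves %||% gf_waves(models)
  if (is.na(n_waves))
    abort("supply n_waves for mixed-model inputs")
  run <- function() {
    noise <- gf_noise(models, S, n_waves)
    ym <- gf_ymean(models, intervention$x_y, intervention$x_m, S, noise,
                   n_waves)
    tibble::tibble(wave = seq_len(ncol(ym)), mean = colMeans(ym))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# Effects at the three interventions needed for SDE and SIE, with common
# random numbers across interventions within one evaluation.
gf_effects_point <- function(models, contrast, S, n_waves) {
  x <- contrast[1]; xref <- contrast[2]
  noise <- gf_noise(models, S, n_waves)
  a <- gf_ymean(models, x_y = x, x_m = xref, S, noise, n_waves)
  b <- gf_ymean(models, x_y = xref, x_m = xref, S, noise, n_waves)
  cc <- gf_ymean(models, x_y = x, x_m = x, S, noise, n_waves)
  tibble::tibble(wave = seq_len(ncol(a)),
                 sde = colMeans(a) - colMeans(b),
                 sie = colMeans(cc) - colMeans(a))
}

fit_backend <- function(panel, backend, fit_args) {
  switch(backend,
    glm = do.call(fit_glm_sequence, c(list(panel = panel), fit_args)),
    mixed = do.call(fit_mixed, c(list(panel = panel), fit_args)),
    lgm = do.call(fit_lgm, c(list(panel = panel), fit_args)))
}

backend_effects <- function(fit, contrast, S, n_waves, effect_method) {
  if (inherits(fit, "sepmed_lgm") && effect_method == "analytic") {
    eff <- lgm_effects(as_lgm_spec(fit), contrast = contrast)
    tibble::tibble(wave = eff$wave, sde = eff$sde, sie = eff$sie)
  } else {
    gf_effects_point(fit, contrast, S, n_waves)
  }
}

#' Estimate separable effects from panel data
#'
#' The full estimator: fits the chosen backend on the panel, evaluates the
#' mediational g-formula at the three interventions needed for the separable
#' direct and indirect effects on the difference scale (sharing random
#' numbers across interventions, so `sde + sie` equals the total-effect
#' contrast by construction), and attaches percentile cluster-bootstrap
#' standard errors and confidence intervals from `B` subject-level resamples,
#' refitting the backend on every resample.
#'
#' For the latent growth backend, `effect_method = "analytic"` evaluates the
#' effects exactly from the fitted structural coefficients (the closed form
#' of the linear-LGM g-formula integral); `"montecarlo"` draws latent factors
#' per simulated subject. The two agree up to Monte-Carlo error.
#'
#' @param panel A balanced panel tibble (`id, wave, x, m, y`).
#' @param backend `"glm"`, `"mixed"` or `"lgm"`.
#' @param contrast `c(x, xref)`: exposure levels compared.
#' @param S Monte-Carlo subjects per g-formula evaluation (>= 10,000 for
#'   production; smaller values warn).
#' @param B Bootstrap replicates (0 for point estimates only).
#' @param ci_level Nominal coverage of the percentile intervals.
#' @param seed Integer seed governing all randomness (Monte-Carlo draws and
#'   bootstrap resampling).
#' @param effect_method Effect evaluation for the lgm backend (see Details).
#' @param ... Passed to the backend fitter ([fit_glm_sequence()],
#'   [fit_mixed()], [fit_lgm()]), e.g. `pool`, `lag_order`, `omit_eta0m`,
#'   `omit_lagged_outcome`, family labels.
#' @return A `sepmed_estimate` tibble: one row per wave with `sde`, `sie`,
#'   `total`, `prop_mediated`, and (when `B > 0`) bootstrap `*_se`, `*_lo`,
#'   `*_hi` columns. Metadata (backend, S, B, seed, contrast) is stored in
#'   attributes and surfaced by [glance()].
#' @examples
#' panel <- simulate_lgm(lgm_spec(), n = 200, seed = 1)
#' est <- estimate_effects(panel, backend = "lgm", B = 0,
#'                         effect_method = "analytic", seed = 1)
#' @export
estimate_effects <- function(panel, backend = c("glm", "mixed", "lgm"),
                             contrast = c(1, 0), S = 10000, B = 500,
                             ci_level = 0.95, seed = NULL,
                             effect_method = c("montecarlo", "analytic"),
                             ...) {
  backend <- match.arg(backend)
  effect_method <- match.arg(effect_method)
  contrast <- check_contrast(contrast)
  panel <- validate_panel(panel)
  fit_args <- list(...)
  n_waves <- max(panel$wave)
  needs_mc <- !(backend == "lgm" && effect_method == "analytic")
  if (needs_mc && S < 10000)
    warn("S below 10,000: Monte-Carlo error may dominate; use S >= 10,000 for production runs")
  ids <- unique(panel$id)
  # balanced panel sorted by (id, wave): subject i occupies a contiguous
  # block of n_waves rows, so cluster resampling is pure row indexing
  row_of <- matrix(seq_len(nrow(panel)), nrow = n_waves)
  point_of <- function(pnl) {
    fit <- fit_backend(pnl, backend, fit_args)
    backend_effects(fit, contrast, S, n_waves, effect_method)
  }
  run <- function() {
    point <- point_of(panel)
    boot <- NULL
    if (B > 0) {
      boot <- purrr::map(seq_len(B), function(b) {
        withr::with_seed(child_seed(seed %||% 0L, b), {
          take <- sample(length(ids), length(ids), replace = TRUE)
          pnl <- panel[as.vector(row_of[, take]), ]
          pnl$id <- rep(seq_along(take), each = n_waves)
          # resample of a validated panel is valid by construction
          attr(pnl, "sepmed_validated") <- TRUE
          point_of(pnl)
        })
      })
    }
    assemble_estimate(point, boot, ci_level, backend, S, B, seed, contrast,
                      length(ids), effect_method)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

assemble_estimate <- function(point, boot, ci_level, backend, S, B, seed,
                              contrast, n_subjects, effect_method) {
  out <- point
  out$total <- out$sde + out$sie
  out$prop_mediated <- proportion_mediated(out$sde, out$sie)
  if (!is.null(boot)) {
    al <- (1 - ci_level) / 2
    bs <- function(col) vapply(boot, function(b) b[[col]], point$sde)
    for (col in c("sde", "sie")) {
      mat <- bs(col) # waves x B
      if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
      out[[paste0(col, "_se")]] <- apply(mat, 1, sd)
      out[[paste0(col, "_lo")]] <- apply(mat, 1, quantile, probs = al)
      out[[paste0(col, "_hi")]] <- apply(mat, 1, quantile, probs = 1 - al)
    }
  }
  structure(out,
            backend = backend, S = S, B = B, seed = seed,
            contrast = contrast, ci_level = ci_level,
            n_subjects = n_subjects, effect_method = effect_method,
            class = c("sepmed_estimate", class(point)))
}

#' Proportion of the total effect carried by the mediator
#'
#' The proportion mediated is the separable indirect effect divided by the
#' total effect, `sie / (sde + sie)`. Undefined (returned as `NA`) when the
#' total effect is zero.
#'
#' @param sde,sie Separable direct and indirect effects (vectorised), or
#'   `sde` may be a `sepmed_estimate`, in which case its per-wave effects are
#'   used and `sie` is ignored.
#' @param wave Optional wave filter when `sde` is an estimate object.
#' @return Numeric vector of proportions.
#' @examples
#' proportion_mediated(-0.765, -0.011)
#' @export
proportion_mediated <- function(sde, sie = NULL, wave = NULL) {
  if (inherits(sde, "sepmed_estimate")) {
    est <- sde
    if (!is.null(wave)) est <- est[est$wave %in% wave, ]
    sie <- est$sie
    sde <- est$sde
  }
  total <- sde + sie
  ifelse(abs(total) < .Machine$double.eps^0.5, NA_real_, sie / total)
}
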