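# Estimation backends for the g-formula: per-wave GLM sequences, linear
# mixed-effect models (via lme4), and the latent growth model by Gaussian
# maximum likelihood on its model-implied moments.

r_family <- function(label) {
  switch(label,
    "gaussian-identity" = gaussian(),
    "binomial-logit" = binomial(),
    "gamma-log" = Gamma(link = "log"),
    abort(sprintf("unknown family label '%s'", label)))
}

# Lagged long-format design; lags before wave 1 are coded 0, which is
# algebraically identical to the wave-1 equations simply not containing the
# lagged terms (the coefficients multiply zeros). Assumes the (id, wave)
# ordering guaranteed by validate_panel(), so lags are plain vector shifts.
add_lags <- function(panel, lag_order = 1L) {
  n <- nrow(panel)
  for (k in seq_len(lag_order)) {
    shift <- function(v) c(rep(0, k), v[seq_len(n - k)])
    mk <- shift(panel$m)
    yk <- shift(panel$y)
    first <- panel$wave <= k
    mk[first] <- 0
    yk[first] <- 0
    panel[[paste0("m_lag", k)]] <- mk
    panel[[paste0("y_lag", k)]] <- yk
  }
  panel
}

glm_sigma <- function(fit, family) {
  if (family == "gaussian-identity") {
    # residual mean squared error, on the SD scale
    sqrt(sum(fit$residuals^2) / fit$df.residual)
  } else if (family == "gamma-log") {
    # squared coefficient of variation (Pearson dispersion)
    sum((fit$y - fit$fitted.values)^2 / fit$fitted.values^2) / fit$df.residual
  } else {
    1
  }
}

seq_model <- function(fit, family) {
  cf <- coef(fit)
  if (any(!is.finite(cf)))
    abort("non-finite coefficients in a sequence model (separation?)")
  list(coef = cf, sigma = glm_sigma(fit, family), family = family)
}

# one conditional model of the sequence; gaussian-identity takes a direct
# least-squares path (these fits sit inside the bootstrap loop)
fit_seq_model <- function(data, resp, rhs, family) {
  # constant regressors (e.g. structurally absent lags coded 0 at every
  # retained wave) carry no information and are dropped, mirroring the
  # convention that variables with zero or negative wave subscripts are not
  # present in the model
  keep <- vapply(rhs, function(v) length(unique(data[[v]])) > 1, logical(1))
  rhs <- rhs[keep]
  if (family == "gaussian-identity") {
    X <- cbind(`(Intercept)` = 1, as.matrix(data[rhs]))
    f <- stats::lm.fit(X, data[[resp]])
    cf <- f$coefficients
    if (any(!is.finite(cf)))
      abort("non-finite coefficients in a sequence model (collinearity?)")
    list(coef = cf,
         sigma = sqrt(sum(f$residuals^2) / (length(f$residuals) - f$rank)),
         family = family)
  } else {
    fml <- as.formula(paste(resp, "~", paste(rhs, collapse = " + ")))
    seq_model(glm(fml, family = r_family(family), data = data), family)
  }
}

#' Fit the per-wave GLM sequence used by the mediational g-formula
#'
#' Step 1 of the g-formula algorithm: parametric models for the mediator and
#' the outcome conditional on the exposure and their histories,
#' \eqn{f_M(M_t | X, \bar M_{t-1}, \bar Y_{t-1})} and
#' \eqn{f_Y(Y_t | X, \bar M_t, \bar Y_{t-1})}. By default one model per
#' process is fitted with coefficients pooled across waves (lagged terms are
#' absent from the wave-1 equations); with `pool = FALSE` a separate model is
#' fitted at every wave, conditioning on up to `lag_order` lags of each
#' process (`lag_order = Inf` conditions on the full history, which is the
#' correctly specified choice when the data carry subject-level random
#' effects). Gaussian residual scales are estimated by the residual mean
#' squared error.
#'
#' @param panel A balanced panel tibble (`id, wave, x, m, y`).
#' @param family_m,family_y Family labels (`"gaussian-identity"`,
#'   `"binomial-logit"`, `"gamma-log"`).
#' @param pool Share coefficients across waves (default) or fit per wave.
#' @param lag_order Number of lags of each process to condition on
#'   (`>= 1`; `Inf` for full history, only with `pool = FALSE`).
#' @param omit_lagged_outcome Drop the lagged outcome from the mediator
#'   models (the "moderate misspecification" switch for mixed-mechanism
#'   data).
#' @return An object of class `sepmed_seq` holding the per-wave mediator and
#'   outcome models.
#' @examples
#' panel <- simulate_mixed(mixed_spec(), n = 200, n_waves = 3, seed = 1)
#' fit <- fit_glm_sequence(panel)
#' @export
fit_glm_sequence <- function(panel, family_m = "gaussian-identity",
                             family_y = "gaussian-identity", pool = TRUE,
                             lag_order = 1L, omit_lagged_outcome = FALSE) {
  panel <- validate_panel(panel)
  stopifnot(lag_order >= 1)
  n_waves <- max(panel$wave)
  if (pool) {
    if (!is.finite(lag_order))
      abort("pooled fitting requires a finite lag_order")
    df <- add_lags(panel, lag_order)
    lag_terms <- function(drop_y = FALSE) {
      tm <- paste0("m_lag", seq_len(lag_order))
      ty <- if (drop_y) character() else paste0("y_lag", seq_len(lag_order))
      c(tm, ty)
    }
    mm <- fit_seq_model(df, "m", c("x", lag_terms(omit_lagged_outcome)),
                        family_m)
    om <- fit_seq_model(df, "y", c("x", "m", lag_terms(FALSE)), family_y)
    med <- rep(list(mm), n_waves)
    out <- rep(list(om), n_waves)
  } else {
    wide <- panel_wide(panel)
    med <- out <- vector("list", n_waves)
    for (t in seq_len(n_waves)) {
      k <- min(lag_order, t - 1)
      lags <- function(drop_y = FALSE) {
        tm <- if (k > 0) paste0("m_lag", seq_len(k)) else character()
        ty <- if (k > 0 && !drop_y) paste0("y_lag", seq_len(k))
              else character()
        c(tm, ty)
      }
      dft <- wide
      for (j in seq_len(k)) {
        dft[[paste0("m_lag", j)]] <- wide[[paste0("m", t - j)]]
        dft[[paste0("y_lag", j)]] <- wide[[paste0("y", t - j)]]
      }
      dft$m <- wide[[paste0("m", t)]]
      dft$y <- wide[[paste0("y", t)]]
      med[[t]] <- fit_seq_model(dft, "m", c("x", lags(omit_lagged_outcome)),
                                family_m)
      out[[t]] <- fit_seq_model(dft, "y", c("x", "m", lags(FALSE)), family_y)
    }
  }
  structure(list(med = med, out = out, n_waves = n_waves,
                 lag_order = lag_order, pool = pool,
                 family_m = family_m, family_y = family_y),
            class = "sepmed_seq")
}

panel_wide <- function(panel) {
  tidyr::pivot_wider(panel, id_cols = c("id", "x"), names_from = "wave",
                     values_from = c("m", "y"), names_sep = "")
}

#' Fit the cross-lagged linear mixed-effect mediation models
#'
#' Maximum-likelihood fits (via [lme4::lmer()]) of the mediator and outcome
#' models of [mixed_spec()]: the mediator model carries a random intercept,
#' the outcome model a random intercept and random slopes on the concurrent
#' and lagged mediator. Wave-1 rows enter with their lagged regressors coded
#' zero, which matches the wave-1 equations having no lagged terms. The
#' random-effect covariance is estimated diagonal (default) or with a free
#' covariance within the outcome block; fitting the two processes separately
#' structurally forces the mediator/outcome cross-block covariance to zero,
#' which is also the only regime in which the separable effects are
#' identified.
#'
#' @inheritParams fit_glm_sequence
#' @param random_structure `"diagonal"` (independent random effects) or
#'   `"block"` (free covariance among the outcome-model random effects).
#' @return An object of class `sepmed_mixed` with elements `estimates` (the
#'   [mixed_spec()] fields), `convergence`, `singular`, and the underlying
#'   lme4 fits.
#' @examples
#' panel <- simulate_mixed(mixed_spec(), n = 300, n_waves = 3, seed = 1)
#' fit <- fit_mixed(panel)
#' @export
fit_mixed <- function(panel, random_structure = c("diagonal", "block"),
                      omit_lagged_outcome = FALSE) {
  panel <- validate_panel(panel)
  random_structure <- match.arg(random_structure)
  df <- add_lags(panel, 1L)
  f_m <- if (omit_lagged_outcome) m ~ x + m_lag1 + (1 | id)
         else m ~ x + m_lag1 + y_lag1 + (1 | id)
  f_y <- if (random_structure == "diagonal")
    y ~ x + m + m_lag1 + y_lag1 + (1 | id) + (0 + m | id) + (0 + m_lag1 | id)
  else
    y ~ x + m + m_lag1 + y_lag1 + (1 + m + m_lag1 | id)
  fm <- lme4::lmer(f_m, data = df, REML = FALSE)
  fy <- lme4::lmer(f_y, data = df, REML = FALSE)
  bm <- lme4::fixef(fm)
  by <- lme4::fixef(fy)
  phi <- matrix(0, 4, 4, dimnames = list(.re_names, .re_names))
  vc_m <- as.data.frame(lme4::VarCorr(fm))
  phi["b0", "b0"] <- vc_m$vcov[vc_m$grp == "id"][1]
  vc_y <- lme4::VarCorr(fy)
  if (random_structure == "diagonal") {
    vy <- as.data.frame(vc_y)
    vy <- vy[vy$grp != "Residual", ]
    pick <- function(v) vy$vcov[vy$var1 == v & is.na(vy$var2)][1]
    phi["g0", "g0"] <- pick("(Intercept)")
    phi["gM", "gM"] <- pick("m")
    phi["g_lag_m", "g_lag_m"] <- pick("m_lag1")
  } else {
    blk <- vc_y$id[c("(Intercept)", "m", "m_lag1"),
                   c("(Intercept)", "m", "m_lag1")]
    phi[2:4, 2:4] <- blk
  }
  singular <- lme4::isSingular(fm) || lme4::isSingular(fy)
  if (singular)
    warn("singular random-effect fit: some variance components are on the boundary")
  est <- list(
    beta0 = unname(bm["(Intercept)"]), beta_x = unname(bm["x"]),
    beta_lag_m = unname(bm["m_lag1"]),
    beta_lag_y = if (omit_lagged_outcome) 0 else unname(bm["y_lag1"]),
    gamma0 = unname(by["(Intercept)"]), gamma_x = unname(by["x"]),
    gamma_m = unname(by["m"]), gamma_lag_m = unname(by["m_lag1"]),
    gamma_lag_y = unname(by["y_lag1"]),
    phi = phi,
    sigma_eps_m = sigma(fm), sigma_eps_y = sigma(fy),
    family_m = "gaussian-identity", family_y = "gaussian-identity")
  structure(list(estimates = est, singular = singular,
                 loglik = as.numeric(stats::logLik(fm) + stats::logLik(fy)),
                 fits = list(mediator = fm, outcome = fy)),
            class = "sepmed_mixed")
}

#' @importFrom stats sigma logLik
NULL

#' Coerce a fitted model to a mechanism specification
#'
#' Turns a fitted backend into the corresponding [mixed_spec()] or
#' [lgm_spec()], so that fitted parameters can be plugged into the
#' forward-simulation engines and effect oracles.
#'
#' @param fit A `sepmed_mixed` or `sepmed_lgm` object.
#' @return A specification object.
#' @export
as_mixed_spec <- function(fit) {
  stopifnot(inherits(fit, "sepmed_mixed"))
  do.call(mixed_spec, fit$estimates)
}

#' @rdname as_mixed_spec
#' @export
as_lgm_spec <- function(fit) {
  stopifnot(inherits(fit, "sepmed_lgm"))
  est <- fit$estimates
  est$psi14 <- NULL # fitting-structure parameter, not part of the mechanism
  do.call(lgm_spec, est)
}

# ---- latent growth model: Gaussian ML on implied moments -------------------

# Model-implied mean (given x) and covariance of the stacked observations
# (M_1..M_T, Y_1..Y_T) under the structural equations of lgm_spec().
lgm_implied_moments <- function(est, x) {
  lam <- est$lambda
  tt <- length(lam)
  G <- diag(4)
  G[4, 1] <- est$gamma12
  G[4, 2] <- est$gamma13
  psi_z <- diag(est$zeta_sd^2)
  # optional free covariance between the eta0M and eta1Y disturbances
  # (used by the path-omitting fit structure; zero in the generating model)
  psi14 <- est$psi14 %||% 0
  psi_z[1, 4] <- psi_z[4, 1] <- psi14
  psi <- G %*% psi_z %*% t(G)
  L <- rbind(cbind(1, lam, 0, 0), cbind(0, 0, 1, lam))
  sigma <- L %*% psi %*% t(L) +
    diag(c(rep(est$eps_sd_m^2, tt), rep(est$eps_sd_y^2, tt)))
  eta_mu <- c(est$beta00 + est$beta01 * x,
              est$beta10 + est$beta11 * x,
              est$gamma00 + est$gamma01 * x, 0)
  eta_mu[4] <- est$gamma10 + est$gamma11 * x + est$gamma12 * eta_mu[1] +
    est$gamma13 * eta_mu[2]
  list(mu = as.vector(L %*% eta_mu), sigma = sigma)
}

lgm_group_stats <- function(panel) {
  wide <- panel_wide(panel)
  tt <- max(panel$wave)
  cols <- c(paste0("m", seq_len(tt)), paste0("y", seq_len(tt)))
  lapply(c(0, 1), function(xv) {
    z <- as.matrix(wide[wide$x == xv, cols])
    n <- nrow(z)
    zbar <- colMeans(z)
    zc <- sweep(z, 2, zbar)
    list(n = n, mean = zbar, cov = crossprod(zc) / n)
  })
}

lgm_par_to_est <- function(par, lambda, omit_eta0m, free_psi14 = omit_eta0m) {
  p <- as.list(par)
  est <- list(beta00 = p$beta00, beta01 = p$beta01, beta10 = p$beta10,
              beta11 = p$beta11, gamma00 = p$gamma00, gamma01 = p$gamma01,
              gamma10 = p$gamma10, gamma11 = p$gamma11,
              gamma12 = if (omit_eta0m) 0 else p$gamma12,
              gamma13 = p$gamma13, lambda = lambda,
              zeta_sd = exp(unlist(p[paste0("log_zeta", 1:4)],
                                   use.names = FALSE)),
              eps_sd_m = exp(p$log_eps_m), eps_sd_y = exp(p$log_eps_y))
  est$psi14 <- if (free_psi14) p$psi14 else 0
  est
}

lgm_neg2ll <- function(par, stats, lambda, omit_eta0m, free_psi14) {
  est <- lgm_par_to_est(par, lambda, omit_eta0m, free_psi14)
  val <- 0
  for (i in 1:2) {
    g <- stats[[i]]
    mom <- lgm_implied_moments(est, x = i - 1)
    ch <- tryCatch(chol(mom$sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    si <- chol2inv(ch)
    delta <- g$mean - mom$mu
    val <- val + g$n * (logdet + sum(si * g$cov) +
                          drop(delta %*% si %*% delta))
  }
  if (!is.finite(val)) 1e10 else val
}

# Two-stage starting values: per-subject OLS of each trajectory on (1, lambda)
# gives latent-factor scores; the structural regressions on those scores give
# coefficient starts (attenuated by measurement error, but close enough for a
# quasi-Newton refinement). Exact when the data are noiseless.
lgm_two_stage <- function(panel, lambda, omit_eta0m, free_psi14 = omit_eta0m) {
  wide <- panel_wide(panel)
  tt <- length(lambda)
  A <- cbind(1, lambda)
  P <- solve(crossprod(A), t(A))
  Mm <- as.matrix(wide[paste0("m", seq_len(tt))])
  Ym <- as.matrix(wide[paste0("y", seq_len(tt))])
  etam <- Mm %*% t(P) # columns: eta0M, eta1M scores
  etay <- Ym %*% t(P)
  x <- wide$x
  resid_var <- function(obs, eta) {
    r <- obs - eta %*% t(A)
    max(sum(r^2) / (nrow(obs) * (tt - 2)), 0)
  }
  s2_em <- resid_var(Mm, etam)
  s2_ey <- resid_var(Ym, etay)
  reg <- function(yv, X) {
    f <- lm.fit(cbind(1, X), yv)
    list(coef = f$coefficients, s2 = mean(f$residuals^2),
         resid = f$residuals)
  }
  r0m <- reg(etam[, 1], cbind(x))
  r1m <- reg(etam[, 2], cbind(x))
  r0y <- reg(etay[, 1], cbind(x))
  X1y <- if (omit_eta0m) cbind(x, etam[, 2]) else cbind(x, etam[, 1], etam[, 2])
  r1y <- reg(etay[, 2], X1y)
  # factor-score variances include measurement noise; subtract its share
  fsvar <- diag(P %*% t(P))
  z1 <- max(r0m$s2 - s2_em * fsvar[1], 1e-4)
  z2 <- max(r1m$s2 - s2_em * fsvar[2], 1e-4)
  z3 <- max(r0y$s2 - s2_ey * fsvar[1], 1e-4)
  z4 <- max(r1y$s2 - s2_ey * fsvar[2], 1e-4)
  cf1y <- r1y$coef
  par <- c(beta00 = unname(r0m$coef[1]), beta01 = unname(r0m$coef[2]),
           beta10 = unname(r1m$coef[1]), beta11 = unname(r1m$coef[2]),
           gamma00 = unname(r0y$coef[1]), gamma01 = unname(r0y$coef[2]),
           gamma10 = unname(cf1y[1]), gamma11 = unname(cf1y[2]))
  if (!omit_eta0m) {
    par <- c(par, gamma12 = unname(cf1y[3]), gamma13 = unname(cf1y[4]))
  } else {
    par <- c(par, gamma13 = unname(cf1y[3]))
  }
  par <- c(par,
           log_zeta1 = log(sqrt(z1)), log_zeta2 = log(sqrt(z2)),
           log_zeta3 = log(sqrt(z3)), log_zeta4 = log(sqrt(z4)),
           log_eps_m = log(sqrt(max(s2_em, 1e-8))),
           log_eps_y = log(sqrt(max(s2_ey, 1e-8))))
  if (free_psi14)
    par <- c(par, psi14 = mean(r0m$resid * r1y$resid))
  c(par, degenerate = as.numeric(s2_em < 1e-10 && s2_ey < 1e-10))
}

#' Fit the parallel-process latent growth mediation model
#'
#' Gaussian maximum likelihood on the model-implied joint distribution of the
#' stacked observations \eqn{(M_1..M_T, Y_1..Y_T)} given the exposure, with
#' fixed time loadings. Means and covariance are derived algebraically from
#' the measurement and structural equations of [lgm_spec()]; optimisation is
#' quasi-Newton (BFGS) from two-stage (factor-score regression) starting
#' values, with random restarts on non-convergence. `omit_eta0m = TRUE` fixes
#' \eqn{\gamma_{12} = 0}, i.e. drops the mediator latent intercept from the
#' outcome latent-slope equation — the "moderate misspecification" structure.
#'
#' @inheritParams fit_glm_sequence
#' @param lambda Fixed time loadings; defaults to `wave - 1`.
#' @param omit_eta0m Fix `gamma12` at zero?
#' @param free_psi14 Free the covariance between the mediator latent-intercept
#'   disturbance and the outcome latent-slope disturbance. Defaults to
#'   `omit_eta0m`: an analyst who drops the structural path typically still
#'   lets those latents covary, reading the association as residual
#'   correlation rather than causation (with `omit_eta0m = TRUE` and
#'   `free_psi14 = FALSE` the fit is forced to distort `gamma13` instead).
#'   Not identified, hence unavailable, together with a free `gamma12`.
#' @param max_restarts Random restarts allowed on non-convergence.
#' @param se Also compute asymptotic standard errors from the numerical
#'   Hessian at the optimum (element `se`; log scale for scale parameters)?
#' @return An object of class `sepmed_lgm` with elements `estimates` (the
#'   [lgm_spec()] fields), `loglik`, `implied` (fitted moments by exposure
#'   group), and `convergence`.
#' @examples
#' panel <- simulate_lgm(lgm_spec(), n = 300, seed = 1)
#' fit <- fit_lgm(panel)
#' fit$estimates$gamma12
#' @export
fit_lgm <- function(panel, lambda = NULL, omit_eta0m = FALSE,
                    free_psi14 = omit_eta0m, max_restarts = 5L, se = FALSE) {
  panel <- validate_panel(panel)
  if (free_psi14 && !omit_eta0m)
    abort("free_psi14 is not identified together with a free gamma12")
  tt <- max(panel$wave)
  if (is.null(lambda)) lambda <- as.numeric(seq_len(tt) - 1)
  stopifnot(length(lambda) == tt)
  start_full <- lgm_two_stage(panel, lambda, omit_eta0m, free_psi14)
  degenerate <- start_full[["degenerate"]] > 0.5
  start <- start_full[setdiff(names(start_full), "degenerate")]
  if (degenerate) {
    est <- lgm_par_to_est(start, lambda, omit_eta0m, free_psi14)
    est$eps_sd_m <- 0; est$eps_sd_y <- 0
    est$zeta_sd <- pmax(exp(start[paste0("log_zeta", 1:4)]), 0)
    return(structure(
      list(estimates = est, loglik = NA_real_,
           implied = lapply(0:1, function(x) lgm_implied_moments(est, x)),
           convergence = list(code = 0L, degenerate = TRUE, restarts = 0L)),
      class = "sepmed_lgm"))
  }
  stats <- lgm_group_stats(panel)
  best <- NULL
  for (r in 0:max_restarts) {
    p0 <- if (r == 0) start else start + rnorm(length(start), 0, 0.2)
    opt <- tryCatch(
      optim(p0, lgm_neg2ll, stats = stats, lambda = lambda,
            omit_eta0m = omit_eta0m, free_psi14 = free_psi14,
            method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
      best$restarts <- r
    }
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best))
    abort("latent growth fit failed: optimiser error on every restart")
  if (best$convergence != 0)
    warn(sprintf("latent growth fit did not converge (optim code %d)",
                 best$convergence))
  names(best$par) <- names(start)
  est <- lgm_par_to_est(best$par, lambda, omit_eta0m, free_psi14)
  n_tot <- stats[[1]]$n + stats[[2]]$n
  ses <- NULL
  if (se) {
    # objective is -2 log L, so the observed information is H / 2
    H <- stats::optimHess(best$par, lgm_neg2ll, stats = stats,
                          lambda = lambda, omit_eta0m = omit_eta0m,
                          free_psi14 = free_psi14)
    vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0))
      ses <- setNames(sqrt(diag(vc)), names(best$par))
  }
  structure(
    list(estimates = est, se = ses,
         loglik = -0.5 * (best$value + n_tot * 2 * tt * log(2 * pi)),
         implied = lapply(0:1, function(x) lgm_implied_moments(est, x)),
         convergence = list(code = best$convergence, degenerate = FALSE,
                            restarts = best$restarts)),
    class = "sepmed_lgm")
}

#' @importFrom stats lm.fit
NULL
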