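#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an effect estimate into one row per (wave, effect)
#'
#' @param x A `sepmed_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `wave`, `effect` (`"sde"`/`"sie"`),
#'   `estimate`, and when bootstrapped `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.sepmed_estimate <- function(x, ...) {
  df <- tibble::as_tibble(as.data.frame(x))
  out <- tidyr::pivot_longer(df[c("wave", "sde", "sie")],
                             cols = c("sde", "sie"),
                             names_to = "effect", values_to = "estimate")
  if ("sde_se" %in% names(df)) {
    se <- tidyr::pivot_longer(df[c("wave", "sde_se", "sie_se")],
                              cols = -1, names_to = "effect",
                              values_to = "std.error")
    lo <- tidyr::pivot_longer(df[c("wave", "sde_lo", "sie_lo")],
                              cols = -1, names_to = "effect",
                              values_to = "conf.low")
    hi <- tidyr::pivot_longer(df[c("wave", "sde_hi", "sie_hi")],
                              cols = -1, names_to = "effect",
                              values_to = "conf.high")
    out$std.error <- se$std.error
    out$conf.low <- lo$conf.low
    out$conf.high <- hi$conf.high
  }
  out
}

#' @export
glance.sepmed_estimate <- function(x, ...) {
  tibble::tibble(backend = attr(x, "backend"),
                 effect_method = attr(x, "effect_method"),
                 n_subjects = attr(x, "n_subjects"),
                 n_waves = nrow(x),
                 S = attr(x, "S"), B = attr(x, "B"),
                 ci_level = attr(x, "ci_level"),
                 seed = attr(x, "seed") %||% NA_integer_)
}

#' Tidy fitted backend coefficients
#'
#' @param x A `sepmed_mixed` or `sepmed_lgm` fit.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.sepmed_mixed <- function(x, ...) {
  est <- x$estimates
  fixed <- est[vapply(est, function(v) is.numeric(v) && length(v) == 1,
                      logical(1))]
  out <- tibble::tibble(term = names(fixed),
                        estimate = unlist(fixed, use.names = FALSE))
  re <- tibble::tibble(term = paste0("var_", .re_names),
                       estimate = diag(est$phi))
  dplyr::bind_rows(out, re)
}

#' @export
glance.sepmed_mixed <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, singular = x$singular)
}

#' @export
tidy.sepmed_lgm <- function(x, ...) {
  est <- x$estimates
  scalars <- est[vapply(est, function(v) is.numeric(v) && length(v) == 1,
                        logical(1))]
  dplyr::bind_rows(
    tibble::tibble(term = names(scalars),
                   estimate = unlist(scalars, use.names = FALSE)),
    tibble::tibble(term = paste0("zeta_sd", 1:4), estimate = est$zeta_sd))
}

#' @export
glance.sepmed_lgm <- function(x, ...) {
  tibble::tibble(logLik = x$loglik,
                 converged = x$convergence$code == 0,
                 degenerate = x$convergence$degenerate,
                 restarts = x$convergence$restarts)
}

#' @exportS3Method base::print
print.sepmed_estimate <- function(x, ...) {
  cat(sprintf("<separable-effect estimates: backend %s, S = %s, B = %s>\n",
              attr(x, "backend"), attr(x, "S"), attr(x, "B")))
  print(tibble::as_tibble(as.data.frame(x)))
  invisible(x)
}
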