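#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_errorbar geom_hline facet_wrap labs position_dodge
#' @export
ggplot2::autoplot

#' Plot true separable effects across waves
#'
#' @param object A `sepmed_effects` tibble (from [lgm_effects()],
#'   [mixed_effects_closed()] or [mixed_effects_asymptotic()]).
#' @param ... Unused.
#' @return A ggplot object: one line per effect over waves.
#' @export
autoplot.sepmed_effects <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(as.data.frame(object))[
    c("wave", "sde", "sie")],
    cols = c("sde", "sie"), names_to = "effect", values_to = "value")
  ggplot(df, aes(x = .data$wave, y = .data$value,
                 colour = toupper(.data$effect))) +
    geom_line() + geom_point() +
    labs(x = "wave", y = "effect (difference scale)", colour = NULL)
}

#' Plot estimated separable effects with bootstrap intervals
#'
#' @param object A `sepmed_estimate`.
#' @param ... Unused.
#' @return A ggplot object: per-wave point estimates, with error bars when
#'   bootstrap intervals are present.
#' @export
autoplot.sepmed_estimate <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$wave, y = .data$estimate,
                      colour = toupper(.data$effect))) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_point(position = position_dodge(width = 0.2)) +
    labs(x = "wave", y = "estimate", colour = NULL)
  if ("conf.low" %in% names(df))
    p <- p + geom_errorbar(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                           width = 0.15, position = position_dodge(width = 0.2))
  p
}

#' Plot simulation-study metrics per wave
#'
#' @param object A `sepmed_study` report.
#' @param metric One of `"mean_est"`, `"rel_bias"`, `"rmse"`, `"coverage"`.
#' @param ... Unused.
#' @return A ggplot object; for `mean_est` the scenario truth is overlaid as
#'   a dashed line.
#' @export
autoplot.sepmed_study <- function(object, metric = "mean_est", ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  p <- ggplot(df, aes(x = .data$wave, y = .data[[metric]],
                      colour = toupper(.data$effect))) +
    geom_line() + geom_point() +
    labs(x = "wave", y = metric, colour = NULL)
  if (metric == "mean_est")
    p <- p + geom_line(aes(y = .data$truth), linetype = 2)
  if (metric == "coverage")
    p <- p + geom_hline(yintercept = 0.95, linetype = 3)
  p
}
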