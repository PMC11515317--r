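# Panel and report serialisation. Panels travel as long-format CSV with
# header id,wave,x,m,y[,covariate...]; reports as CSV with a JSON metadata
# sidecar.

#' Validate and normalise a longitudinal panel
#'
#' Checks the panel contract — columns `id, wave, x, m, y` present, no
#' missing cells, balanced design (every subject observed at every wave),
#' binary exposure constant within subject — and returns the panel sorted by
#' `(id, wave)`. Surplus columns are preserved as baseline covariates.
#'
#' @param panel A data frame.
#' @return The validated panel as a tibble, in `(id, wave)` order.
#' @export
validate_panel <- function(panel) {
  if (isTRUE(attr(panel, "sepmed_validated"))) return(panel)
  required <- c("id", "wave", "x", "m", "y")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols))
    abort(sprintf("panel is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  panel <- tibble::as_tibble(panel)
  if (anyNA(panel[required]))
    abort("panel contains missing values in id/wave/x/m/y")
  if (!all(panel$x %in% c(0, 1)))
    abort("x: exposure must be binary 0/1")
  panel <- dplyr::arrange(panel, .data$id, .data$wave)
  waves <- sort(unique(panel$wave))
  if (!identical(as.integer(waves), seq_len(max(waves))))
    abort("wave: waves must be 1..T")
  counts <- dplyr::count(panel, .data$id)
  if (dplyr::n_distinct(counts$n) != 1 || counts$n[1] != length(waves))
    abort("panel is unbalanced: every subject must have exactly one row per wave")
  xs <- dplyr::summarise(dplyr::group_by(panel, .data$id),
                         k = dplyr::n_distinct(.data$x))
  if (any(xs$k != 1))
    abort("x: exposure must be constant within subject")
  attr(panel, "sepmed_validated") <- TRUE
  panel
}

#' Read or write a panel as long-format CSV
#'
#' @param path CSV file path with header `id,wave,x,m,y[,covariate...]`.
#' @param panel A panel tibble.
#' @return `read_panel()` returns the validated panel sorted by `(id, wave)`;
#'   `write_panel()` returns `path` invisibly.
#' @export
read_panel <- function(path) {
  validate_panel(utils::read.csv(path))
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(validate_panel(panel), path, row.names = FALSE)
  invisible(path)
}

#' Import a wide (one row per subject) panel
#'
#' Converts SEM-style wide data with columns `m1..mT`, `y1..yT` (plus `id`
#' and `x`) into the long panel format used throughout the package.
#'
#' @param wide A data frame with columns `id`, `x`, `m<t>` and `y<t>`.
#' @return A long panel tibble.
#' @export
read_panel_wide <- function(wide) {
  wide <- tibble::as_tibble(wide)
  long <- tidyr::pivot_longer(wide, cols = dplyr::matches("^[my][0-9]+$"),
                              names_to = c(".value", "wave"),
                              names_pattern = "([my])([0-9]+)")
  long$wave <- as.integer(long$wave)
  validate_panel(long)
}

#' Write an effect estimate or study report to CSV with a JSON sidecar
#'
#' The table is written at six significant digits; run metadata (backend,
#' Monte-Carlo size, bootstrap replicates, seed, contrast) goes to
#' `<path>.json`.
#'
#' @param report A `sepmed_estimate` or `sepmed_study` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- attributes(report)
  meta <- meta[setdiff(names(meta), c("row.names", "names", "class"))]
  meta$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  meta$package_version <- as.character(utils::packageVersion("sepmed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
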