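# CSV readers/writers with schema validation, plus JSON config sidecars.
#
# Schemas: loss curves (replicate_id, passage, fraction, n_events), events
# (fsc, ssc, fl1, label optional), growth (time_min, od, label optional),
# competition (initial_fraction, final_fraction, replicate_id optional).
# Headers mandatory, UTF-8, '.' decimal. Fractions round-trip at full double
# precision (writers use 15 significant digits).

stop_schema <- function(path, msg) stop("schema error in '", path, "': ", msg)

check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_schema(path, paste("missing column(s):", paste(miss, collapse = ", ")))
}

check_fraction_col <- function(df, col, path) {
  bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
  if (length(bad))
    stop_schema(path, paste0("column '", col, "' outside [0, 1] at row ",
                             bad[1L], " (value ", df[[col]][bad[1L]], ")"))
}

write_csv_precise <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = NA))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write plasmid-loss curves
#'
#' Loss curves are long CSV tables with columns `replicate_id`, `passage`
#' (non-negative integers, strictly increasing within a replicate),
#' `fraction` (in `[0, 1]`) and optional `n_events`.
#'
#' @param path CSV file path.
#' @return `read_loss_curves()`: the validated `data.frame`.
#' @export
read_loss_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("replicate_id", "passage", "fraction"), path)
  if (!"n_events" %in% names(df)) df$n_events <- NA_real_
  check_fraction_col(df, "fraction", path)
  bad <- which(!is.finite(df$passage) | df$passage < 0 |
                 df$passage != round(df$passage))
  if (length(bad))
    stop_schema(path, paste0("'passage' not a non-negative integer at row ",
                             bad[1L]))
  for (r in split(df, df$replicate_id)) {
    if (is.unsorted(r$passage, strictly = TRUE))
      stop_schema(path, paste0("passages not strictly increasing for replicate '",
                               r$replicate_id[1L], "'"))
  }
  df
}

#' @rdname read_loss_curves
#' @param curves Loss-curve `data.frame`.
#' @export
write_loss_curves <- function(curves, path) {
  stopifnot(all(c("replicate_id", "passage", "fraction") %in% names(curves)))
  if (!"n_events" %in% names(curves)) curves$n_events <- NA_real_
  write_csv_precise(curves[, c("replicate_id", "passage", "fraction",
                               "n_events")], path)
}

#' Read and write flow-cytometry event tables
#'
#' Event tables are CSVs with positive columns `fsc`, `ssc`, `fl1` and an
#' optional `label` column.
#'
#' @param path CSV file path.
#' @return `read_events()`: the validated `data.frame`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("fsc", "ssc", "fl1"), path)
  for (col in c("fsc", "ssc", "fl1")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad))
      stop_schema(path, paste0("column '", col, "' must be positive; row ",
                               bad[1L]))
  }
  df
}

#' @rdname read_events
#' @param events Event `data.frame`.
#' @export
write_events <- function(events, path) {
  check_event_table(events)
  write_csv_precise(events, path)
}

#' Read and write optical-density growth curves
#'
#' Growth curves are CSVs with columns `time_min` (strictly increasing),
#' `od` (> 0) and optional `label`.
#'
#' @param path CSV file path.
#' @return `read_growth_curve()`: the validated `data.frame`.
#' @export
read_growth_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("time_min", "od"), path)
  if (any(!is.finite(df$od) | df$od <= 0))
    stop_schema(path, "'od' must be positive")
  if (is.unsorted(df$time_min, strictly = TRUE))
    stop_schema(path, "'time_min' must be strictly increasing")
  df
}

#' @rdname read_growth_curve
#' @param curve Growth-curve `data.frame`.
#' @export
write_growth_curve <- function(curve, path) {
  stopifnot(all(c("time_min", "od") %in% names(curve)))
  write_csv_precise(curve, path)
}

#' Read and write competition dilution series
#'
#' Competition series are CSVs with columns `initial_fraction`,
#' `final_fraction` (both in `[0, 1]`) and optional `replicate_id`.
#'
#' @param path CSV file path.
#' @return `read_competition()`: the validated `data.frame`.
#' @export
read_competition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("initial_fraction", "final_fraction"), path)
  check_fraction_col(df, "initial_fraction", path)
  check_fraction_col(df, "final_fraction", path)
  df
}

#' @rdname read_competition
#' @param series Competition `data.frame`.
#' @export
write_competition <- function(series, path) {
  stopifnot(all(c("initial_fraction", "final_fraction") %in% names(series)))
  write_csv_precise(series, path)
}

#' Write posterior draws and summaries
#'
#' @param fit A `psk_posterior` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`draws.csv`, `summary.csv`).
#' @export
write_posterior <- function(fit, dir) {
  stopifnot(inherits(fit, "psk_posterior"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "draws.csv")
  p2 <- file.path(dir, "summary.csv")
  write_csv_precise(fit$draws, p1)
  write_csv_precise(fit$summary, p2)
  invisible(c(draws = p1, summary = p2))
}

#' Read and write run configuration (JSON)
#'
#' Configuration sidecars record every generator/fit setting for provenance.
#'
#' @param path JSON file path.
#' @return `read_config()`: the configuration as a named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config Named list of settings.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
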