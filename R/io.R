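# Delimited-text readers/writers for signals, markers and labels, plus
# structured (YAML) round-tripping of pipeline configurations. All on-disk
# formats are plain text: a header row, a strictly increasing time_s column,
# and tab- or comma-separated values (auto-detected on read).

#' Write a signals table to delimited text
#'
#' @param x Tibble with `time_s` plus channel columns.
#' @param path Output file path.
#' @param delim Field delimiter (tab by default).
#' @export
write_signals <- function(x, path, delim = "\t") {
  utils::write.table(x, path, sep = delim, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @noRd
detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a signals table from delimited text
#'
#' Parses tab- or comma-separated text (auto-detected) with a header row
#' whose first column is `time_s`. Validates that time is strictly
#' increasing and regularly sampled within 1\%; the inferred sampling rate
#' is attached as attribute `"fs"`.
#'
#' @param path Input file path.
#' @return Tibble with `time_s` plus channel columns.
#' @export
read_signals <- function(path) {
  delim <- detect_delim(path)
  first <- strsplit(readLines(path, n = 1), delim, fixed = TRUE)[[1]]
  if (!any(is.na(suppressWarnings(as.numeric(first))))) {
    abort(sprintf("%s: missing header row", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "time_s") abort("first column must be `time_s`")
  fs <- infer_fs(df$time_s)  # errors on non-monotone or irregular time
  out <- tibble::as_tibble(df)
  attr(out, "fs") <- fs
  out
}

#' Read a state-label table
#'
#' @param path Input file path (columns `time_s`, `state`, optionally
#'   `strategy`).
#' @param scheme Label vocabulary for the `state` factor.
#' @return Tibble with `time_s`, `state` (factor), `strategy`.
#' @export
read_labels <- function(path, scheme = c("six", "four")) {
  scheme <- match.arg(scheme)
  df <- read_signals_text(path)
  stopifnot(all(c("time_s", "state") %in% names(df)))
  df$state <- factor(df$state, levels = sts_states(scheme))
  if (!"strategy" %in% names(df)) df$strategy <- NA_character_
  tibble::as_tibble(df)
}

#' @noRd
read_signals_text <- function(path) {
  delim <- detect_delim(path)
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a synthetic trial to delimited text files
#'
#' Writes `<prefix>_signals`, `<prefix>_markers` and `<prefix>_labels`
#' (tab-separated) plus a `<prefix>_config.yaml` sidecar into `dir`.
#'
#' @param trial An `sts_trial` from [generate_trial()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the trial's strategy.
#' @return Named character vector of the written paths.
#' @export
write_trial <- function(trial, dir, prefix = trial$strategy) {
  stopifnot(inherits(trial, "sts_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    signals = file.path(dir, paste0(prefix, "_signals.tsv")),
    markers = file.path(dir, paste0(prefix, "_markers.tsv")),
    labels = file.path(dir, paste0(prefix, "_labels.tsv")),
    config = file.path(dir, paste0(prefix, "_config.yaml"))
  )
  write_signals(trial$signals, paths[["signals"]])
  write_signals(trial$markers, paths[["markers"]])
  utils::write.table(trial$labels, paths[["labels"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  yaml::write_yaml(synth_config_to_list(trial$config), paths[["config"]])
  invisible(paths)
}

#' @noRd
synth_config_to_list <- function(config) {
  out <- unclass(config)
  W <- out$true_spatial
  out$true_spatial <- list(muscles = rownames(W), synergies = colnames(W),
                           values = as.numeric(W))
  lapply(out, function(v) if (is.numeric(v) && !is.null(names(v)))
    as.list(v) else v)
}

#' @noRd
synth_config_from_list <- function(x) {
  known <- names(formals(synth_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown synth config key(s): ", paste(unknown, collapse = ", ")))
  }
  W <- x$true_spatial
  x$true_spatial <- matrix(as.numeric(W$values), nrow = length(W$muscles),
                           dimnames = list(W$muscles, W$synergies))
  x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  do.call(synth_config, x)
}

#' Save a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$synth <- synth_config_to_list(config$synth)
  out$kalman <- unclass(config$kalman)
  out$forecast <- unclass(config$forecast)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys (at the top level or inside any sub-config) are rejected.
#'
#' @param path YAML file written by [save_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  x$synth <- synth_config_from_list(x$synth)
  kk <- setdiff(names(x$kalman), names(formals(kalman_config)))
  if (length(kk) > 0) abort(paste0("unknown kalman config key(s): ",
                                   paste(kk, collapse = ", ")))
  x$kalman <- do.call(kalman_config, x$kalman)
  fk <- setdiff(names(x$forecast), c(names(formals(forecast_config))))
  if (length(fk) > 0) abort(paste0("unknown forecast config key(s): ",
                                   paste(fk, collapse = ", ")))
  fc <- x$forecast
  fc$strides <- unlist(fc$strides)
  x$forecast <- do.call(forecast_config, fc)
  x$split <- unlist(x$split)
  do.call(pipeline_config, x)
}
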