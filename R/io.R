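spike_cols <- c("neuron_id", "receptor", "odorant", "concentration",
                "trial", "spike_time_ms")

#' Read and write spike tables
#'
#' The interchange format is a headed CSV with one row per spike and
#' columns `neuron_id,receptor,odorant,concentration,trial,spike_time_ms`
#' (times in ms, zero at odorant arrival; extra columns are ignored).
#' Rows are sorted by neuron, trial and time on read and on write, so
#' write/read round-trips are stable.
#'
#' @param path File path.
#' @param spikes A spike tibble (as produced by [generate_population()] or
#'   [read_spikes()]).
#' @return `read_spikes()` returns a spike tibble; `write_spikes()`
#'   invisibly returns `spikes`.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_spikes(df)
}

#' @rdname read_spikes
#' @export
write_spikes <- function(spikes, path) {
  spikes <- validate_spikes(spikes)
  readr::write_csv(spikes[spike_cols], path, progress = FALSE)
  invisible(spikes)
}

#' Validate and normalize a spike table
#'
#' Checks the required columns, coerces types, and sorts by neuron, trial
#' and spike time. Errors name any missing column.
#'
#' @param spikes A data frame of spikes.
#' @return The validated, sorted spike tibble.
#' @export
validate_spikes <- function(spikes) {
  missing_cols <- setdiff(spike_cols, names(spikes))
  if (length(missing_cols) > 0) {
    abort(sprintf("Spike table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  spikes <- as_tibble(spikes)
  if (nrow(spikes) == 0) {
    # header-only tables: fix the column types regardless of reader guesses
    spikes$concentration <- as.numeric(spikes$concentration)
    spikes$spike_time_ms <- as.numeric(spikes$spike_time_ms)
  }
  if (!is.numeric(spikes$concentration) || anyNA(spikes$concentration)) {
    abort("`concentration` must be finite numeric (log10 dilution).")
  }
  if (!is.numeric(spikes$spike_time_ms) || any(!is.finite(spikes$spike_time_ms))) {
    abort("`spike_time_ms` must be finite numeric.")
  }
  spikes$trial <- as.integer(spikes$trial)
  spikes$neuron_id <- as.character(spikes$neuron_id)
  dplyr::arrange(spikes, .data$neuron_id, .data$trial, .data$spike_time_ms)
}

#' Read and write stimulus waveforms
#'
#' Two-column CSV (`time_ms,signal`).
#'
#' @param path File path.
#' @param stim A waveform with columns `time_ms` and `signal`.
#' @return `read_stimulus()` returns a tibble; `write_stimulus()`
#'   invisibly returns `stim`.
#' @export
read_stimulus <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_ms", "signal") %in% names(df))) {
    abort("Stimulus file must have columns `time_ms` and `signal`.")
  }
  as_tibble(df)
}

#' @rdname read_stimulus
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(all(c("time_ms", "signal") %in% names(stim)))
  readr::write_csv(as_tibble(stim)[c("time_ms", "signal")], path,
                   progress = FALSE)
  invisible(stim)
}
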