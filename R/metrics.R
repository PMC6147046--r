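#' First-spike latency of a single train
#'
#' Time of the first spike at or after odorant arrival (t = 0) and inside
#' the response window. The window is closed on the left, so a spike at
#' exactly 0 has latency 0.
#'
#' @param spike_times Numeric spike times, ms relative to odorant arrival.
#' @param response_window Two-element window `(t0, t1)` with `t0 = 0`.
#' @return Latency in ms, or `NA_real_` if no in-window spike.
#' @examples
#' first_spike_latency(c(-3, 5.2, 7.1)) # 5.2
#' @export
first_spike_latency <- function(spike_times, response_window = c(0, 200)) {
  stopifnot(response_window[1] == 0, response_window[2] > 0)
  hit <- spike_times[spike_times >= response_window[1] &
                       spike_times <= response_window[2]]
  if (length(hit) == 0) NA_real_ else min(hit)
}

#' Per-trial first-spike latencies of a spike table
#'
#' @param spikes A spike tibble.
#' @param response_window See [first_spike_latency()].
#' @return A tibble with one row per (receptor, odorant, concentration,
#'   neuron_id, trial) and column `latency_ms` (`NA` when the trial has no
#'   in-window spike).
#' @export
latency_table <- function(spikes, response_window = c(0, 200)) {
  validate_spikes(spikes) |>
    dplyr::group_by(.data$receptor, .data$odorant, .data$concentration,
                    .data$neuron_id, .data$trial) |>
    dplyr::summarise(
      latency_ms = first_spike_latency(.data$spike_time_ms, response_window),
      .groups = "drop"
    )
}

#' Trial-to-trial jitter of first-spike latencies
#'
#' Sample SD (denominator n - 1) of the defined per-trial latencies of one
#' neuron. Trials without an evoked spike are excluded; if fewer than two
#' defined latencies remain the jitter is undefined (`NA`) and a warning
#' reports the count.
#'
#' @param latencies Numeric per-trial latencies (ms), `NA` allowed.
#' @return Jitter in ms or `NA_real_`.
#' @examples
#' trial_to_trial_jitter(c(2, 4)) # sqrt(2)
#' @export
trial_to_trial_jitter <- function(latencies) {
  ok <- latencies[!is.na(latencies)]
  if (length(ok) < 2) {
    warn(sprintf(
      "Jitter undefined: %d defined latency(ies), %d undefined trial(s).",
      length(ok), sum(is.na(latencies))
    ))
    return(NA_real_)
  }
  sd(ok)
}

#' Neuron-to-neuron jitter of first-spike latencies
#'
#' Sample SD across neurons of the per-neuron median first-spike latency at
#' one stimulus condition.
#'
#' @param latency_medians Per-neuron median latencies (ms), `NA` allowed.
#' @return Jitter in ms, or `NA_real_` if fewer than two neurons have a
#'   defined median.
#' @export
neuron_to_neuron_jitter <- function(latency_medians) {
  ok <- latency_medians[!is.na(latency_medians)]
  if (length(ok) < 2) return(NA_real_)
  sd(ok)
}

#' Minimum interspike interval of one neuron
#'
#' Per-trial evoked interspike interval, summarized as the median across
#' trials. `mode = "first_to_second"` (default) takes the interval between
#' the first and second in-window spikes; `mode = "global_min"` the
#' smallest interval between consecutive in-window spikes. The reciprocal
#' of the interval (in s) is the maximum instantaneous firing rate.
#'
#' @param spikes Spike tibble of one neuron (column `trial` splits trials).
#' @param response_window Window of evoked spikes, ms.
#' @param mode `"first_to_second"` or `"global_min"`.
#' @return Median interval in ms, or `NA_real_` if no trial has at least
#'   two in-window spikes.
#' @export
min_interspike_interval <- function(spikes, response_window = c(0, 200),
                                    mode = c("first_to_second", "global_min")) {
  mode <- match.arg(mode)
  per_trial <- split(spikes$spike_time_ms, spikes$trial)
  vals <- vapply(per_trial, function(t) {
    t <- sort(t[t >= response_window[1] & t <= response_window[2]])
    if (length(t) < 2) return(NA_real_)
    if (mode == "first_to_second") t[2] - t[1] else min(diff(t))
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  median(vals, na.rm = TRUE)
}

#' Summary spike-timing statistics per stimulus condition
#'
#' For each (receptor, odorant, concentration) condition: the median across
#' neurons of per-neuron median first-spike latencies; the mean across
#' neurons of per-neuron trial-to-trial jitters; the neuron-to-neuron
#' jitter (SD of per-neuron medians); and the median across neurons of
#' per-neuron minimum interspike intervals.
#'
#' @param spikes A spike tibble.
#' @param response_window Response window, ms (starts at 0).
#' @param mode ISI mode, see [min_interspike_interval()].
#' @return A tibble with one row per condition and columns
#'   `latency_median`, `latency_trial_jitter`, `latency_neuron_jitter`,
#'   `min_isi`, `n_neurons`, `n_trials`.
#' @export
response_stats <- function(spikes, response_window = c(0, 200),
                           mode = "first_to_second") {
  lat <- latency_table(spikes, response_window)
  per_neuron <- lat |>
    dplyr::group_by(.data$receptor, .data$odorant, .data$concentration,
                    .data$neuron_id) |>
    dplyr::summarise(
      med = median(.data$latency_ms, na.rm = TRUE),
      jit = suppressWarnings(trial_to_trial_jitter(.data$latency_ms)),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  isi <- validate_spikes(spikes) |>
    dplyr::group_by(.data$receptor, .data$odorant, .data$concentration,
                    .data$neuron_id) |>
    dplyr::summarise(
      isi = min_interspike_interval(
        dplyr::pick(dplyr::everything()), response_window, mode
      ),
      .groups = "drop"
    )
  dplyr::left_join(
    per_neuron, isi,
    by = c("receptor", "odorant", "concentration", "neuron_id")
  ) |>
    dplyr::group_by(.data$receptor, .data$odorant, .data$concentration) |>
    dplyr::summarise(
      latency_median = median(.data$med, na.rm = TRUE),
      latency_trial_jitter = mean(.data$jit, na.rm = TRUE),
      latency_neuron_jitter = neuron_to_neuron_jitter(.data$med),
      min_isi = median(.data$isi, na.rm = TRUE),
      n_neurons = dplyr::n(),
      n_trials = max(.data$n_trials),
      .groups = "drop"
    )
}

#' Spike probability in a sliding window
#'
#' For each window position, the fraction of trains (neuron x trial) that
#' contain at least one spike in `[t, t + window_len)`. Positions are
#' labelled by the window start.
#'
#' @param spikes A spike tibble (one condition; group beforehand for
#'   several).
#' @param window_len Window length in ms (default 1 ms).
#' @param step Step between window starts, ms.
#' @param range Time range `(t0, t1)` to scan, ms.
#' @return A tibble with columns `time_ms` (window start) and `p`.
#' @export
sliding_psth <- function(spikes, window_len = 1, step = 0.5,
                         range = c(-50, 200)) {
  stopifnot(window_len > 0, step > 0)
  spikes <- validate_spikes(spikes)
  trains <- split(
    spikes$spike_time_ms,
    interaction(spikes$neuron_id, spikes$trial, drop = TRUE)
  )
  if (length(trains) == 0) abort("Empty recording set.")
  starts <- seq(range[1], range[2] - window_len, by = step)
  occupied <- vapply(trains, function(t) {
    t <- sort(t)
    # a window [s, s+w) holds a spike iff the first spike >= s is < s+w
    idx <- findInterval(starts, t, left.open = TRUE) + 1L
    idx <= length(t) & t[pmin(idx, length(t))] < starts + window_len
  }, logical(length(starts)))
  occupied <- matrix(occupied, nrow = length(starts))
  tibble(time_ms = starts, p = rowMeans(occupied))
}
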