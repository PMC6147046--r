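#' Detection accuracy d_a over spike counts
#'
#' Discriminability of odorant-evoked from spontaneous pooled spike counts:
#' the difference of the two means divided by their root-mean-square SD,
#' `d_a = (mean(evoked) - mean(spont)) / sqrt((var(evoked) + var(spont)) / 2)`
#' with sample variances (denominator n - 1). If both variances are zero the
#' result is `Inf` (sign of the mean difference) when the means differ and
#' 0 when all values are identical.
#'
#' @param evoked_counts,spont_counts Integer count vectors (>= 2 values
#'   each).
#' @return d_a (unitless).
#' @examples
#' detection_accuracy(c(2, 3, 4), c(0, 1, 2)) # 2
#' @export
detection_accuracy <- function(evoked_counts, spont_counts) {
  if (length(evoked_counts) < 2 || length(spont_counts) < 2) {
    abort("Both count vectors need at least 2 values to estimate SDs.")
  }
  dm <- mean(evoked_counts) - mean(spont_counts)
  v <- (stats::var(evoked_counts) + stats::var(spont_counts)) / 2
  if (v == 0) {
    if (dm == 0) return(0)
    return(sign(dm) * Inf)
  }
  dm / sqrt(v)
}

#' False-positive rate of an ideal observer at a given d_a
#'
#' Error rate of an equal-variance Gaussian observer whose criterion sits
#' midway between the spontaneous and evoked count means:
#' `FPR = pnorm(-d_a / 2)`. At the detection-accuracy threshold of 5 this
#' is about 0.62%, i.e. below 1%.
#'
#' @param d_a Detection accuracy (>= 0).
#' @return False-positive fraction in (0, 0.5].
#' @examples
#' false_positive_rate(5) # ~0.0062
#' @export
false_positive_rate <- function(d_a) {
  if (any(d_a < 0)) abort("`d_a` must be non-negative.")
  pnorm(-d_a / 2)
}

# sorted spike-time lookup keyed by neuron/trial, for fast window counts
index_trains <- function(spikes) {
  spikes <- validate_spikes(spikes)
  key <- paste(spikes$neuron_id, spikes$trial, sep = "\r")
  trains <- split(spikes$spike_time_ms, key)
  lapply(trains, sort)
}

train_key <- function(neuron_id, trial) paste(neuron_id, trial, sep = "\r")

# spikes of one sorted train in [start, start+len), vectorized over starts
count_in_windows <- function(train, starts, len) {
  if (is.null(train) || length(train) == 0) return(numeric(length(starts)))
  findInterval(starts + len, train, left.open = TRUE) -
    findInterval(starts, train, left.open = TRUE)
}

#' Pooled spike counts for one pool draw
#'
#' The evoked count is the total number of spikes across all pooled
#' (neuron, trial) picks in `[window_start, window_start +
#' integration_time)`. Spontaneous counts come from tiling the baseline
#' window into non-overlapping windows of the same length, each tile's
#' count pooled across the same picks.
#'
#' @param spikes A spike tibble.
#' @param picks Data frame with columns `neuron_id` and `trial`, one row
#'   per pooled pick (repeats allowed).
#' @param window_start Evoked window start, ms.
#' @param integration_time Window length, ms.
#' @param baseline_window Baseline span `(t0, t1)` with `t1 <= 0`, ms.
#' @return A list with `evoked` (single pooled count), `spont_counts`
#'   (one pooled count per baseline tile), `integration_time`,
#'   `window_start` and `pool_size`.
#' @export
pooled_counts <- function(spikes, picks, window_start, integration_time,
                          baseline_window = c(-200, 0)) {
  idx <- index_trains(spikes)
  pooled_counts_indexed(idx, picks, window_start, integration_time,
                        baseline_window)
}

pooled_counts_indexed <- function(idx, picks, window_start, integration_time,
                                  baseline_window) {
  stopifnot(baseline_window[2] <= 0)
  if (diff(baseline_window) < integration_time) {
    abort("Baseline window is shorter than the integration time.")
  }
  keys <- train_key(picks$neuron_id, picks$trial)
  tile_starts <- seq(baseline_window[1],
                     baseline_window[2] - integration_time,
                     by = integration_time)
  evoked <- 0
  spont <- numeric(length(tile_starts))
  for (k in keys) {
    tr <- idx[[k]]
    evoked <- evoked + count_in_windows(tr, window_start, integration_time)
    spont <- spont + count_in_windows(tr, tile_starts, integration_time)
  }
  list(evoked = evoked, spont_counts = spont,
       integration_time = integration_time, window_start = window_start,
       pool_size = nrow(picks))
}

# draw one random pool: neurons with replacement, one random trial each
draw_pool <- function(neurons, trials_by_neuron, pool_size) {
  ns <- sample(neurons, pool_size, replace = TRUE)
  tr <- vapply(ns, function(n) {
    tt <- trials_by_neuron[[n]]
    tt[sample.int(length(tt), 1)]
  }, integer(1))
  tibble(neuron_id = ns, trial = tr)
}

# d_a vs window start for one ensemble of pools (uses current RNG stream)
da_curve_ensemble <- function(idx, neurons, trials_by_neuron, pool_size,
                              integration_time, n_pools, window_starts,
                              baseline_window) {
  tile_starts <- seq(baseline_window[1],
                     baseline_window[2] - integration_time,
                     by = integration_time)
  evoked <- matrix(0, nrow = length(window_starts), ncol = n_pools)
  spont <- numeric(0)
  for (p in seq_len(n_pools)) {
    picks <- draw_pool(neurons, trials_by_neuron, pool_size)
    keys <- train_key(picks$neuron_id, picks$trial)
    ev <- numeric(length(window_starts))
    sp <- numeric(length(tile_starts))
    for (k in keys) {
      tr <- idx[[k]]
      ev <- ev + count_in_windows(tr, window_starts, integration_time)
      sp <- sp + count_in_windows(tr, tile_starts, integration_time)
    }
    evoked[, p] <- ev
    spont <- c(spont, sp)
  }
  vapply(seq_along(window_starts), function(i) {
    detection_accuracy(evoked[i, ], spont)
  }, numeric(1))
}

#' Peak detection accuracy for random neuron pools
#'
#' For each repetition, draws `n_pools` random pools (neurons sampled with
#' replacement, one random trial per pooled neuron), computes d_a at each
#' sliding window position from the pooled evoked counts (one per pool)
#' against baseline-tile spontaneous counts, and takes the maximum over
#' window positions.
#'
#' @param spikes A spike tibble (one condition).
#' @param pool_size Number of pooled neurons (e.g. 23 for OR59b, 8 for
#'   OR22a).
#' @param integration_time Counting-window length, ms.
#' @param n_pools Pools per repetition (default 40).
#' @param n_reps Repetitions (independent pool ensembles).
#' @param window_starts Evoked window starts to scan, ms.
#' @param baseline_window Baseline span for spontaneous counts, ms.
#' @param seed Integer seed (required).
#' @return A tibble with columns `pool_size`, `integration_time`, `rep`,
#'   `peak_da`.
#' @export
peak_detection_accuracy <- function(spikes, pool_size, integration_time,
                                    n_pools = 40, n_reps = 10,
                                    window_starts = seq(0, 45, by = 1),
                                    baseline_window = c(-200, 0), seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  stopifnot(pool_size >= 1)
  spikes <- validate_spikes(spikes)
  idx <- index_trains(spikes)
  meta <- dplyr::distinct(spikes, .data$neuron_id, .data$trial)
  trials_by_neuron <- split(meta$trial, meta$neuron_id)
  neurons <- names(trials_by_neuron)

  with_seed(as.integer(seed), {
    peaks <- vapply(seq_len(n_reps), function(r) {
      da <- da_curve_ensemble(idx, neurons, trials_by_neuron, pool_size,
                              integration_time, n_pools, window_starts,
                              baseline_window)
      max(da[is.finite(da)], -Inf)
    }, numeric(1))
    tibble(pool_size = pool_size, integration_time = integration_time,
           rep = seq_len(n_reps), peak_da = peaks)
  })
}

#' Minimum integration time to exceed a detection-accuracy threshold
#'
#' For each repetition, scans the integration-time grid in ascending order
#' and reports the smallest value whose peak d_a (computed from one
#' ensemble of `n_pools` random pools, maximized over window positions)
#' strictly exceeds `threshold`, or `NA` if the threshold is never
#' exceeded within the grid (capped at 40 ms by default).
#'
#' @inheritParams peak_detection_accuracy
#' @param threshold Detection-accuracy threshold (default 5, i.e. ideal
#'   observer false-positive rate below 1%).
#' @param grid Ascending integration-time grid, ms.
#' @param n_repetitions Number of repetitions (default 50).
#' @return A tibble with columns `repetition` and `min_integration_time`
#'   (`NA` when the threshold was never exceeded).
#' @export
min_integration_time <- function(spikes, pool_size, threshold = 5,
                                 grid = 1:40, n_pools = 40,
                                 n_repetitions = 50,
                                 window_starts = seq(0, 45, by = 1),
                                 baseline_window = c(-200, 0), seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  stopifnot(!is.unsorted(grid), pool_size >= 1)
  spikes <- validate_spikes(spikes)
  idx <- index_trains(spikes)
  meta <- dplyr::distinct(spikes, .data$neuron_id, .data$trial)
  trials_by_neuron <- split(meta$trial, meta$neuron_id)
  neurons <- names(trials_by_neuron)

  with_seed(as.integer(seed), {
    res <- vapply(seq_len(n_repetitions), function(r) {
      for (it in grid) {
        da <- da_curve_ensemble(idx, neurons, trials_by_neuron, pool_size,
                                it, n_pools, window_starts, baseline_window)
        peak <- max(da[is.finite(da)], -Inf)
        if (peak > threshold) return(as.numeric(it))
      }
      NA_real_
    }, numeric(1))
    tibble(repetition = seq_len(n_repetitions), min_integration_time = res)
  })
}

#' Peak-d_a surface over integration times and pool sizes
#'
#' Convenience sweep of [peak_detection_accuracy()] over a grid, returning
#' the mean and SD of peak d_a per cell.
#'
#' @inheritParams peak_detection_accuracy
#' @param integration_times,pool_sizes Grid values.
#' @return A tibble with columns `integration_time`, `pool_size`,
#'   `mean_peak_da`, `sd_peak_da`, `n_reps`; class `da_surface` for
#'   [autoplot()].
#' @export
da_surface <- function(spikes, integration_times = c(1, 2, 4, 8, 16, 32, 64),
                       pool_sizes = c(1, 2, 4, 8, 16, 23, 32, 40),
                       n_pools = 40, n_reps = 5,
                       window_starts = seq(0, 45, by = 1),
                       baseline_window = c(-200, 0), seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  grid <- tidyr::expand_grid(integration_time = integration_times,
                             pool_size = pool_sizes)
  out <- purrr::pmap(grid, function(integration_time, pool_size) {
    peak_detection_accuracy(
      spikes, pool_size, integration_time,
      n_pools = n_pools, n_reps = n_reps, window_starts = window_starts,
      baseline_window = baseline_window,
      seed = seed + 7919L * pool_size + as.integer(integration_time)
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::group_by(.data$integration_time, .data$pool_size) |>
    dplyr::summarise(
      mean_peak_da = mean(.data$peak_da),
      sd_peak_da = sd(.data$peak_da),
      n_reps = dplyr::n(), .groups = "drop"
    )
  class(out) <- c("da_surface", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.da_surface <- function(object, ...) {
  ggplot(object, aes(
    x = .data$pool_size, y = .data$mean_peak_da,
    colour = factor(.data$integration_time),
    group = factor(.data$integration_time)
  )) +
    geom_line() +
    geom_point() +
    labs(
      x = "Pool size (neurons)", y = "Peak detection accuracy (d_a)",
      colour = "Integration\ntime (ms)"
    ) +
    theme_minimal()
}
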