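#' Generate one synthetic ORN spike train
#'
#' Spike times are in ms relative to odorant arrival (negative =
#' pre-stimulus). The pre-stimulus segment is homogeneous Poisson at
#' `spont_rate`, thinned to a refractory floor; spontaneous firing
#' continues after time zero until the first evoked spike. The first
#' evoked spike occurs at `latency_median + N(0, latency_sd)`, clipped
#' below at a transduction floor (2 ms by default; odorant transduction is
#' never faster). Subsequent evoked spikes follow a gamma renewal process
#' (shape 2) whose instantaneous rate decays from `peak_rate` towards
#' `spont_rate` with time constant `adapt_tau`, intervals bounded below by
#' `min_isi`.
#'
#' All stochastic generators in this package require an explicit `seed`.
#'
#' @param params One-row data frame from [response_params()] (or with the
#'   same columns).
#' @param baseline Pre-stimulus duration in ms (>= 0).
#' @param duration Post-stimulus duration in ms (> latency_median).
#' @param seed Integer seed (required).
#' @param neuron_id,trial Labels for the returned rows.
#' @param floor_ms Transduction floor for the first evoked spike, ms.
#' @param refractory Absolute refractory floor between any two spikes, ms.
#'
#' @return A tibble with columns `neuron_id`, `receptor`, `odorant`,
#'   `concentration`, `trial`, `spike_time_ms` (one row per spike, sorted).
#' @examples
#' p <- response_params("OR59b", "methyl butyrate", -4)
#' generate_trial(p, baseline = 100, duration = 200, seed = 1)
#' @export
generate_trial <- function(params, baseline = 200, duration = 200, seed,
                           neuron_id = "n1", trial = 1L,
                           floor_ms = 2, refractory = 1) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  with_seed(as.integer(seed), {
    spikes <- sim_trial_spikes(params, baseline, duration, floor_ms, refractory)
    spike_tibble(params, neuron_id, trial, spikes)
  })
}

# one trial using the current RNG stream (callers own the seed)
sim_trial_spikes <- function(params, baseline, duration, floor_ms = 2,
                             refractory = 1) {
  stopifnot(baseline >= 0, duration > 0)
  if (duration <= params$latency_median) {
    abort("`duration` must exceed the median latency.")
  }
  r_ms <- params$spont_rate / 1000 # spikes per ms

  # first evoked spike: Gaussian-jittered latency, clipped at the floor
  t1 <- max(floor_ms, params$latency_median + rnorm(1, 0, params$latency_sd))

  # spontaneous spikes from -baseline up to the first evoked spike
  spont <- numeric(0)
  if (r_ms > 0) {
    span <- baseline + t1
    n <- rpois(1, r_ms * span)
    spont <- sort(runif(n, -baseline, t1))
    spont <- thin_refractory(spont, refractory)
    spont <- spont[spont < t1 - refractory]
  }

  # evoked renewal train: gamma(2) intervals at the decaying rate,
  # bounded below by min_isi
  evoked <- t1
  t <- t1
  repeat {
    rate <- (params$spont_rate +
      (params$peak_rate - params$spont_rate) * exp(-(t - t1) / params$adapt_tau)) / 1000
    isi <- max(params$min_isi, rgamma(1, shape = 2, rate = 2 * rate))
    t <- t + isi
    if (t >= duration) break
    evoked <- c(evoked, t)
  }
  c(spont, evoked)
}

thin_refractory <- function(times, refractory) {
  if (length(times) < 2) return(times)
  keep <- times[1]
  last <- times[1]
  for (x in times[-1]) {
    if (x - last >= refractory) {
      keep <- c(keep, x)
      last <- x
    }
  }
  keep
}

spike_tibble <- function(params, neuron_id, trial, spikes) {
  tibble(
    neuron_id = neuron_id,
    receptor = params$receptor,
    odorant = params$odorant,
    concentration = params$concentration,
    trial = as.integer(trial),
    spike_time_ms = spikes
  )
}

#' Generate a synthetic ORN population recording
#'
#' Draws `n_neurons` neurons whose median latencies are perturbed around
#' the calibrated [response_params()] value with SD
#' `neuron_sd_scale * latency_sd`, then simulates `n_trials` trials per
#' neuron with [generate_trial()]'s model. With the default
#' `neuron_sd_scale = 1`, neuron-to-neuron jitter is comparable to
#' trial-to-trial jitter, as observed in paired ORN recordings.
#'
#' A single root `seed` governs all randomness; sub-draws consume the RNG
#' stream sequentially (neurons in order, then trials within neuron), so
#' identical arguments reproduce the identical recording set.
#'
#' @param receptor,odorant,concentration Condition labels, see
#'   [response_params()].
#' @param n_neurons,n_trials Population and repetition sizes (>= 1).
#' @param seed Integer root seed (required).
#' @param baseline,duration Pre-/post-stimulus span in ms.
#' @param neuron_sd_scale Inter-neuron latency variability as a multiple of
#'   the trial-to-trial SD.
#' @param id_prefix Prefix for generated neuron ids.
#' @param base_params Optional one-row parameter table used instead of
#'   [response_params()] (for non-default latency/jitter settings).
#' @param ... Passed to [response_params()] (e.g. `spont_rate`).
#'
#' @return A spike tibble (one row per spike) covering
#'   `n_neurons * n_trials` trains.
#' @examples
#' pop <- generate_population("OR59b", "methyl butyrate", -4,
#'   n_neurons = 3, n_trials = 5, seed = 1
#' )
#' dplyr::count(pop, neuron_id, trial)
#' @export
generate_population <- function(receptor, odorant, concentration,
                                n_neurons, n_trials, seed,
                                baseline = 200, duration = 200,
                                neuron_sd_scale = 1,
                                id_prefix = NULL, base_params = NULL, ...) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  stopifnot(n_neurons >= 1, n_trials >= 1)
  base <- base_params %||%
    response_params(receptor, odorant, concentration, ...)
  floor_ms <- orn_defaults()$transduction_floor_ms
  prefix <- id_prefix %||% paste0(sub("OR", "", base$receptor), "_n")

  with_seed(as.integer(seed), {
    out <- vector("list", n_neurons * n_trials)
    k <- 1L
    for (i in seq_len(n_neurons)) {
      p_i <- base
      p_i$latency_median <- max(
        floor_ms,
        base$latency_median + rnorm(1, 0, neuron_sd_scale * base$latency_sd)
      )
      for (j in seq_len(n_trials)) {
        spikes <- sim_trial_spikes(p_i, baseline, duration, floor_ms = floor_ms)
        out[[k]] <- spike_tibble(p_i, sprintf("%s%02d", prefix, i), j, spikes)
        k <- k + 1L
      }
    }
    dplyr::bind_rows(out)
  })
}
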