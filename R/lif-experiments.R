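#' Synthetic ORN input for one network run
#'
#' One trial of each of 8 OR22a and 23 OR59b neurons at the given odorant
#' and concentration, generated with [generate_population()] (so the
#' odorant-specific latency rank offsets of [response_params()] apply).
#'
#' @param odorant,concentration Stimulus condition.
#' @param seed Integer seed (required).
#' @param n_or22a,n_or59b Pool sizes.
#' @param span Simulation span the trains must fit, ms.
#' @param ... Passed to [generate_population()].
#' @return A spike tibble with 31 single-trial trains.
#' @export
make_orn_input <- function(odorant, concentration, seed,
                           n_or22a = 8, n_or59b = 23,
                           span = c(-10, 50), ...) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  baseline <- -span[1]
  duration <- span[2] - 1
  dplyr::bind_rows(
    generate_population("OR22a", odorant, concentration,
      n_neurons = n_or22a, n_trials = 1, seed = seed,
      baseline = baseline, duration = duration, ...
    ),
    generate_population("OR59b", odorant, concentration,
      n_neurons = n_or59b, n_trials = 1, seed = seed + 1L,
      baseline = baseline, duration = duration, ...
    )
  )
}

#' Classification rate of the network over repeated runs
#'
#' Simulates `n_runs` independent synthetic input sets per odorant and
#' scores each run with the KC exclusivity rule ([classify_trial()]).
#' Reports per-run outcomes; summarize with [glance()] (per-odorant
#' percent correct and KC first-spike latency summary).
#'
#' Run seeds derive from the root seed as
#' `seed + 100003 * odorant_index + run`.
#'
#' @param odorants Odorant labels to test.
#' @param concentration log10 dilution (intermediate concentrations,
#'   around 1e-3, give the documented rank offsets headroom).
#' @param n_runs Simulation runs per odorant.
#' @param seed Integer root seed (required).
#' @param spec A [network_spec()].
#' @param dt,span See [simulate_network()].
#' @param ... Passed to [make_orn_input()] (e.g. `spont_rate`).
#' @return An object of class `lif_classification`: tibble with columns
#'   `odorant`, `run`, `label`, `correct`, `kc_first_spike`.
#' @export
classification_rate <- function(odorants = c("methyl butyrate", "ethyl acetate"),
                                concentration = -3, n_runs = 100, seed,
                                spec = default_network(), dt = 0.025,
                                span = c(-10, 50), ...) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  stopifnot(n_runs >= 1)
  out <- purrr::map(seq_along(odorants), function(oi) {
    od <- odorants[oi]
    purrr::map(seq_len(n_runs), function(run) {
      input <- make_orn_input(od, concentration,
                              seed = as.integer(seed) + 100003L * oi + run,
                              span = span, ...)
      res <- simulate_network(spec, input, dt = dt, span = span)
      tibble(odorant = od, run = run, label = res$classification,
             correct = res$classification == od,
             kc_first_spike = res$kc_first_spike)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(out) <- c("lif_classification", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.lif_classification <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lif_classification")
  out
}

#' @exportS3Method generics::glance
glance.lif_classification <- function(x, ...) {
  x |>
    dplyr::group_by(.data$odorant) |>
    dplyr::summarise(
      rate_pct = 100 * mean(.data$correct),
      n_runs = dplyr::n(),
      kc_latency_median = median(.data$kc_first_spike[.data$correct]),
      kc_latency_max = max(.data$kc_first_spike[.data$correct]),
      .groups = "drop"
    )
}

#' @exportS3Method ggplot2::autoplot
autoplot.lif_classification <- function(object, ...) {
  ggplot(
    dplyr::filter(object, .data$correct),
    aes(x = .data$odorant, y = .data$kc_first_spike)
  ) +
    geom_boxplot(width = 0.4, outlier.shape = NA) +
    geom_jitter(width = 0.1, alpha = 0.4) +
    labs(x = NULL, y = "KC first-spike latency (ms)",
         title = "Correct runs") +
    theme_minimal()
}

#' Shift the spike trains of one receptor type in time
#'
#' @param spikes A spike tibble.
#' @param shift Time shift in ms (positive = later).
#' @param receptor Receptor type to shift (the other is untouched).
#' @return The shifted spike tibble.
#' @export
shift_trains <- function(spikes, shift, receptor = "OR22a") {
  dplyr::mutate(spikes, spike_time_ms = ifelse(
    .data$receptor == !!receptor,
    .data$spike_time_ms + shift, .data$spike_time_ms
  ))
}

#' Time-shift sweep of network classification
#'
#' For each run, one synthetic input set is generated; then for every
#' shift the OR22a trains are translated in time (OR59b unchanged, spikes
#' leaving the simulation span are dropped) and the network re-simulated.
#' The classification rate per shift is the percentage of runs labelled as
#' the generating odorant, so a shift that reverses the receptor rank
#' order collapses the rate.
#'
#' @inheritParams classification_rate
#' @param odorant Generating odorant.
#' @param shifts Shift grid, ms (default -4 to 4 in 0.2 ms steps).
#' @return A tibble with columns `shift_ms`, `rate_pct`, `n_runs`; class
#'   `shift_sweep` for [autoplot()].
#' @export
time_shift_sweep <- function(odorant = "methyl butyrate", concentration = -3,
                             shifts = seq(-4, 4, by = 0.2), n_runs = 20,
                             seed, spec = default_network(), dt = 0.025,
                             span = c(-10, 50), ...) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  stopifnot(all(is.finite(shifts)))
  inputs <- purrr::map(seq_len(n_runs), function(run) {
    make_orn_input(odorant, concentration,
                   seed = as.integer(seed) + run, span = span, ...)
  })
  out <- purrr::map(shifts, function(sh) {
    correct <- vapply(inputs, function(input) {
      shifted <- shift_trains(input, sh, "OR22a") |>
        dplyr::filter(.data$spike_time_ms >= span[1],
                      .data$spike_time_ms <= span[2])
      res <- simulate_network(spec, shifted, dt = dt, span = span)
      res$classification == odorant
    }, logical(1))
    tibble(shift_ms = sh, rate_pct = 100 * mean(correct), n_runs = n_runs)
  }) |> purrr::list_rbind()
  class(out) <- c("shift_sweep", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.shift_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$shift_ms, y = .data$rate_pct)) +
    geom_hline(yintercept = 50, linetype = "dashed") +
    geom_line() +
    geom_point() +
    labs(x = "OR22a time shift (ms)", y = "Correct classification (%)") +
    ylim(0, 100) +
    theme_minimal()
}

#' Calibrate ORN -> PN weights
#'
#' Returns the minimal synaptic amplitude at which a perfectly synchronous
#' volley of `n_inputs` spikes drives the postsynaptic LIF neuron to
#' threshold within `window` ms of the volley's arrival, times a safety
#' `margin` that absorbs the latency jitter of real (non-synchronous)
#' volleys. Closed form: a unit-amplitude exponential current (decay
#' `tau_syn`) deflects the membrane by
#' `c(t) = tau_syn * tau_m / (tau_m - tau_syn) * (exp(-t/tau_m) - exp(-t/tau_syn))`,
#' so the required amplitude is `(v_threshold - v_rest) / (n * c(window))`.
#'
#' @param n_inputs Number of pooled input spikes (23 OR59b or 8 OR22a).
#' @param params Postsynaptic [lif_params()].
#' @param window Required time-to-spike after volley arrival, ms.
#' @param margin Multiplicative safety factor.
#' @return Synaptic amplitude (mV/ms per spike).
#' @export
calibrate_weights <- function(n_inputs, params = lif_params(), window = 2,
                              margin = 1.5) {
  stopifnot(n_inputs >= 1, window > 0)
  gap <- params$v_threshold - params$v_rest
  margin * gap / (n_inputs * psp_deflection(window, params))
}

# membrane deflection at time t after a unit-amplitude exponential
# synaptic current lands (double-exponential PSP)
psp_deflection <- function(t, params = lif_params()) {
  tm <- params$tau_m
  ts <- params$tau_syn
  if (abs(tm - ts) < 1e-9) return(t * exp(-t / tm))
  ts * tm / (tm - ts) * (exp(-t / tm) - exp(-t / ts))
}
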