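# tiny deterministic spike-table builders used across tests

spike_rows <- function(neuron_id, times, receptor = "OR59b",
                       odorant = "methyl butyrate", concentration = -4,
                       trial = 1L) {
  tibble::tibble(
    neuron_id = neuron_id, receptor = receptor, odorant = odorant,
    concentration = concentration, trial = as.integer(trial),
    spike_time_ms = times
  )
}

# uniform-random small spike table (test-local RNG, independent of the
# package's generators)
random_spike_table <- function(seed, n_neurons = 3, n_trials = 2,
                               n_spikes = 6, t_range = c(-50, 100)) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_neurons), function(i) {
      dplyr::bind_rows(lapply(seq_len(n_trials), function(j) {
        spike_rows(sprintf("n%d", i),
                   sort(stats::runif(n_spikes, t_range[1], t_range[2])),
                   trial = j)
      }))
    }))
  })
}

# parameter row with full manual control (same columns as response_params)
manual_params <- function(latency_median, latency_sd = 0, min_isi = 2,
                          peak_rate = 300, spont_rate = 0, adapt_tau = 20,
                          receptor = "OR59b", odorant = "methyl butyrate",
                          concentration = -3) {
  tibble::tibble(
    receptor = receptor, odorant = odorant, concentration = concentration,
    latency_median = latency_median, latency_sd = latency_sd,
    min_isi = min_isi, peak_rate = peak_rate, spont_rate = spont_rate,
    adapt_tau = adapt_tau
  )
}

# deterministic synchronous-volley ORN input for the network (8 OR22a at
# t22, 23 OR59b at t59)
volley_input <- function(t22, t59, concentration = -3) {
  dplyr::bind_rows(
    spike_rows(sprintf("a%02d", 1:8), rep(t22, 8), receptor = "OR22a",
               concentration = concentration),
    spike_rows(sprintf("b%02d", 1:23), rep(t59, 23), receptor = "OR59b",
               concentration = concentration)
  )
}
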