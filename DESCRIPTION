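Package: spikerank
Title: Spike-Timing Precision and Rank-Order Odor Coding in Olfactory Receptor Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing millisecond-precise odorant-evoked spiking in
    Drosophila olfactory receptor neurons (ORNs). Provides a calibrated
    synthetic spike-train generator emulating concentration-dependent
    first-spike latencies, trial-to-trial jitter and minimum interspike
    intervals of OR59b and OR22a neurons; spike-timing metrics (first-spike
    latency, jitter, sliding-window spike probability, stimulus rise time); a
    pooled signal-detection analysis of odorant-onset detection (detection
    accuracy d_a over spike counts, integration-time and pool-size sweeps,
    minimum integration time, Gaussian-observer false-positive mapping); a
    concentration-invariant odorant classifier based on latency or
    interspike-interval differences between receptor types; and a
    rank-order-sensitive leaky integrate-and-fire model of the mushroom-body
    circuit with feedforward inhibition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
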