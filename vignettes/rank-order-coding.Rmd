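---
title: "Millisecond spike-timing metrics and rank-order odor coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Millisecond spike-timing metrics and rank-order odor coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikerank)
library(dplyr)
```

## The scientific problem

Insects track odors in turbulent plumes where concentration changes on a
millisecond timescale. That is only possible if the first synapse of the
olfactory system — the olfactory receptor neurons (ORNs) — fires fast and
precisely. In *Drosophila*, ORNs expressing OR59b (ab2 sensilla, converging
on glomerulus DM4, about 23 neurons) and OR22a (ab3, DM2, about 8 neurons)
respond to fast odorant pulses with first-spike latencies down to ~3 ms and
trial-to-trial jitter down to ~0.19 ms at high concentrations, degrading to
tens of milliseconds at low concentrations. Two computational consequences
follow, and this package implements both analyses end to end:

1. **Onset detection.** Because ~23 OR59b (or ~8 OR22a) neurons converge
   onto shared projection neurons, a downstream decoder can pool their
   spikes. Pooled spike counts separate odorant-evoked from spontaneous
   activity (detection accuracy $d_a$) within integration windows shorter
   than a single neuron's interspike interval.
2. **Identity coding.** The *relative* first-spike latency between
   receptor types (OR59b leads for ethyl acetate; OR22a leads, slightly,
   for methyl butyrate) is roughly concentration-invariant, so a single
   latency-difference threshold — or a small rank-order-sensitive spiking
   network — can classify the odorant across orders of magnitude of
   concentration.

All analyses run on a calibrated synthetic spike-train generator, so the
whole pipeline is testable without any recordings. Spike tables are plain
tibbles (`neuron_id, receptor, odorant, concentration, trial,
spike_time_ms`, times in ms with zero at odorant arrival), read and
written as CSV by `read_spikes()`/`write_spikes()`.

## The synthetic generator and what it emulates

`response_params(receptor, odorant, concentration)` interpolates three
summary statistics log-linearly in log10 concentration between a low
anchor at $10^{-7}$ and a high anchor at $10^{-2}$:

| quantity | low anchor | high anchor | emulated observation |
|---|---|---|---|
| median first-spike latency | 50 ms | 3.5 ms | 18–55 ms (low) to 3–4.4 ms (high) |
| trial-to-trial jitter (SD) | 30 ms | 0.25 ms | 4.36–106 ms to 0.19–0.49 ms |
| minimum interspike interval | 20 ms | 2 ms | shortest evoked ISI, 1/peak rate |

Log-linear interpolation was chosen because the observed ranges span two
orders of magnitude and only range endpoints are reported; it makes all
three statistics monotone in concentration and puts the geometric mean of
the anchors at the midpoint concentration. The low latency anchor sits at
50 ms (not at the 55 ms range edge) so that the odorant offsets below never
push a condition outside the observed range.

Odorant identity enters as fixed latency offsets around the interpolated
base: for ethyl acetate OR22a is 3 ms slower than OR59b; for methyl
butyrate OR59b is 1 ms slower than OR22a (split ±0.5 ms around the base so
the high-concentration medians stay inside 3–4.4 ms). The fastest
calibrated condition — OR22a, methyl butyrate, $10^{-2}$ — bottoms out at
the documented 3 ms minimum latency. Matching ISI factors give the
faster-responding type the higher peak rate. Both offsets are
config-overridable; `orn_defaults()` documents the anchors and the
documented extremes (3 ms, 0.19 ms).

`generate_trial()` draws one train: homogeneous Poisson spontaneous firing
(default 5 spikes/s — spontaneous rates are not printed in the source
data, so a typical ORN value was chosen once) thinned to a 1 ms refractory
floor; a first evoked spike at `latency_median` plus Gaussian jitter,
clipped below at a 2 ms transduction floor (odorant transduction is never
faster than the fastest observed 3 ms response); then a gamma (shape 2)
renewal train whose rate decays from `peak_rate` toward the spontaneous
rate with a 20 ms adaptation constant, intervals floored at `min_isi`.
This model reproduces the three summary statistics independently and
controllably, which is exactly what the downstream analyses consume. It
does **not** emulate burst substructure, ephaptic sensillum coupling,
long-term adaptation, or the real per-neuron diversity of the recordings —
so passing tests demonstrate correctness of the estimators and decoders,
not fidelity to any particular fly.

`generate_population()` adds inter-neuron variability by perturbing each
neuron's median latency with SD equal to `neuron_sd_scale` (default 1)
times the trial SD, reflecting the observation that neuron-to-neuron and
trial-to-trial jitter are comparable. A single root seed drives
everything; sub-draws consume the RNG stream sequentially (neurons, then
trials), and every stochastic entry point demands an explicit seed.

```{r generator}
p <- response_params("OR59b", "methyl butyrate", -4)
p
pop <- generate_population("OR59b", "methyl butyrate", -4,
  n_neurons = 6, n_trials = 10, seed = 1
)
response_stats(pop)
```

## Spike-timing metrics

`first_spike_latency()` returns the first spike at or after time zero
inside the response window (default (0, 200) ms — the source data print no
window, so a span comfortably containing all evoked responses was fixed);
a spike exactly at zero counts (closed left boundary). Trials without an
in-window spike are undefined and excluded-but-counted. Jitter estimators
use the $n-1$ sample SD throughout because the emulated experiments use
~10 trials per condition. Neuron-to-neuron jitter is defined as the SD
across neurons of per-neuron median latencies; no formula is printed for
it in the source, and this definition makes it exactly comparable to the
trial-to-trial SD. The minimum interspike interval defaults to the
first-to-second spike interval (`mode = "global_min"` is available), and
`sliding_psth()` computes the fraction of trains with at least one spike
in a sliding 1 ms window. `rise_time_5_95()` measures the stimulus 5–95%
rise with linear interpolation between samples; `make_stimulus()` builds a
logistic-rise pulse whose analytic 5–95% span equals the requested value
(default 3.6 ms, the stimulator's measured rise time), with time zero at
the 5% crossing — the same clock as the spike tables.

## Onset detection: pooled counts and $d_a$

`detection_accuracy()` implements
$d_a = (\mu_{evoked} - \mu_{spont}) / \sqrt{(\sigma^2_{evoked} + \sigma^2_{spont})/2}$
on pooled spike counts. `false_positive_rate()` maps a $d_a$ to the error
of an equal-variance Gaussian observer with the criterion midway between
the two means, $\Phi(-d_a/2)$; at the working threshold $d_a = 5$ this is
0.62%, i.e. below 1% — which is why 5 is the default detection threshold.

The sampling scheme (the exact scheme used on the original data is not
printed): one *ensemble* is `n_pools` (default 40) random pools, each pool
built by sampling `pool_size` neurons **with replacement** (recorded sets
are smaller than the anatomical pools) and one random trial per neuron.
Each pool contributes one pooled evoked count per window position; the
spontaneous distribution comes from tiling each pool's pre-stimulus
baseline into non-overlapping windows of the same length. $d_a$ is
computed per window position from these two distributions and maximized
over a 1 ms-step sliding window. `min_integration_time()` repeats this for
each integration time on an ascending grid (capped at 40 ms) and reports,
per repetition, the smallest integration time whose peak $d_a$ **strictly
exceeds** the threshold, or `NA` if none does. Degenerate zero-variance
count sets map to 0 (identical) or an `Inf` sentinel (separated), and
infinite values are excluded from peak-taking.

```{r detection}
spk <- generate_population("OR59b", "methyl butyrate", -3,
  n_neurons = 8, n_trials = 6, seed = 31, baseline = 200, duration = 80
)
peak_detection_accuracy(spk, pool_size = 23, integration_time = 2,
  n_reps = 3, window_starts = seq(0, 25, 1), seed = 5
)
```

## Latency-difference classification

`latency_differences()` draws pools per receptor type (23 OR59b, 8 OR22a
by default) and takes, per type, the **earliest** first-spike latency in
the pool — the first spike the converging projection neuron could see,
consistent with the network model below (a per-type median is the natural
alternative and the per-pick table makes it easy to compute). The
difference is fixed as OR22a minus OR59b: positive means OR59b led, i.e.
ethyl acetate. `classify_odorant()` applies a single threshold (strictly
greater ⇒ ethyl acetate; a tie goes to methyl butyrate, documented);
`fit_threshold()` scans the piecewise-constant accuracy function
exhaustively across all concentrations pooled, breaking ties toward the
midpoint of the widest optimal interval. Draws in which a type shows no
evoked spike abstain, and abstentions count as errors — a conservative
accuracy. Note that with spontaneous firing enabled, stray spikes shortly
after onset can masquerade as the pool's earliest "response" and cap the
achievable accuracy at low concentrations; that is a property of the
window rule, not a bug, and disappears at `spont_rate = 0`.

## The rank-order LIF network

Five current-based leaky integrate-and-fire units: PN_X pools the 8 OR22a
trains, PN_Y the 23 OR59b trains; both PNs excite an inhibitory neuron I
and both Kenyon cells, each PN strongly driving "its" KC (PN_X→KC_X,
PN_Y→KC_Y) and weakly the other; I inhibits both KCs (feedforward
inhibition). Membrane dynamics
$dV/dt = -(V - V_{rest})/\tau_m + I_{syn}(t)$ integrate with an
exponential-Euler fixed step of 0.025 ms; each presynaptic spike adds an
exponentially decaying current (amplitude = weight, decay
$\tau_{syn} = 2$ ms) after the connection delay. Defaults (all
overridable): $V_{rest} = V_{reset} = -60$ mV, threshold $-45$ mV,
$\tau_m = 5$ ms (3 ms for I), 2 ms refractory.

The quantitative constants of the original simulations are not published,
so the shipped defaults are **behavior-pinned, not copied**: the test
suite pins the mechanism (rank-order sensitivity, inhibition-dependent
exclusivity, sub-0.05 ms dt-convergence, exact translation invariance),
not the constants. The calibration logic, with `calibrate_weights()`
providing the closed-form PSP arithmetic:

- ORN→PN weights make a synchronous full-pool volley cross threshold
  within 2 ms. The OR59b weight is set below the OR22a weight beyond the
  8:23 pool-size ratio (0.8 vs 3.2 mV/ms) so that both PNs cross threshold
  at a comparable delay after their volley's leading edge; with matched
  total drive the denser 23-spike volley would cross relatively earlier
  and compress the 1 ms methyl butyrate rank offset at the PN stage.
- PN→KC strong:weak ratio 2.5:1 (33 vs 13.2 mV/ms); the weak synapse's
  peak deflection (14.3 mV) stays just below the 15 mV threshold gap, so
  a weak input alone can never fire a KC.
- PN→I is strong (60) so I fires within ~0.3 ms of PN drive, and I→KC
  (−60) is strong enough that inhibition triggered by the *leading* PN
  arrives before the *lagging* PN's strong drive can lift its KC across
  threshold, while the leading KC has already fired.
- Delays are 1 ms per hop except PN→KC at 1.5 ms. With every hop at
  exactly 1 ms the disynaptic inhibition (PN→I→KC) arrives 1 ms plus I's
  integration time after the direct PN→KC drive, which is too late to
  veto the lagging KC when the PN rank lag is near 1 ms; the slightly
  longer direct delay (a longer dendritic path to the KC claw than the
  fast perisomatic inhibition) restores the inhibition-first ordering the
  mechanism requires.

`classify_trial()` scores a run by KC exclusivity within a 50 ms decision
window, first KC spikes only: KC_X alone ⇒ methyl butyrate, KC_Y alone ⇒
ethyl acetate, both or neither ⇒ invalid. `classification_rate()` runs 100
independent synthetic input sets per odorant (intermediate concentration
$10^{-3}$ by default); `time_shift_sweep()` translates only the OR22a
trains over −4…+4 ms in 0.2 ms steps, which preserves the label while the
rank order survives and flips it once the shift reverses the rank.

```{r network}
res <- simulate_network(default_network(),
  make_orn_input("methyl butyrate", -3, seed = 5))
res
cr <- classification_rate(n_runs = 25, seed = 42)
glance(cr)
```

## Numerical choices and degenerate inputs

- Sample SDs use $n-1$ everywhere; medians use R's default interpolation.
- Windows are closed on the left, open on the right for counting
  (`[t, t+\Delta)`), and latency windows are closed on both ends.
- Zero-variance $d_a$: 0 when the distributions are identical, $\pm\infty$
  sentinel otherwise; infinite values are excluded from ensemble peaks.
- Threshold ties: classification uses strict `>`; `fit_threshold()` ties
  break toward the midpoint of the widest optimal interval; `min
  integration time` requires strictly exceeding the threshold.
- Synaptic increments land on the first grid point at or after their
  arrival time (with a 1e-9 ms tolerance absorbing floating-point error),
  which makes common input translations by multiples of dt exact.
- Empty spike tables are legal everywhere except `sliding_psth()` (which
  errors, since the trial denominator is undefined).

## Problem sizes

Recovery tests use 10,000 single-neuron trials (SD estimates then sit
within 2% with large margin); network experiments use 100 runs per
odorant for rates and 10–25 runs for property checks; detection sweeps in
tests use 8-neuron, 6-trial synthetic sets with 30-pool ensembles. These
sizes were chosen so every estimate is comfortably inside its tolerance
while the full suite stays fast.

## Known limitations

- The generator's adaptation constant, burst shape and spontaneous rate
  are declared defaults, not fitted values; analyses that depend on
  sustained-response details (e.g. long-integration $d_a$) inherit them.
- The network is a two-odorant, two-PN, two-KC proof of principle —
  no full mushroom body (~2,000 KCs), no recurrent (APL-style)
  inhibition, no plasticity, no conductance-based synapses, and all
  stochasticity enters through the ORN inputs.
- The classifier handles exactly the two calibrated odorants; multi-odor
  decoding is out of scope.
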