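#' Leaky integrate-and-fire neuron parameters
#'
#' @param v_rest,v_threshold,v_reset Resting, threshold and reset
#'   potentials, mV (`v_reset <= v_rest < v_threshold`).
#' @param tau_m Membrane time constant, ms.
#' @param refractory Absolute refractory period, ms.
#' @param tau_syn Synaptic current decay time constant, ms.
#' @return A list of class `lif_params`.
#' @export
lif_params <- function(v_rest = -60, v_threshold = -45, v_reset = -60,
                       tau_m = 5, refractory = 2, tau_syn = 2) {
  if (!(v_reset <= v_rest && v_rest < v_threshold)) {
    abort("Require v_reset <= v_rest < v_threshold.")
  }
  if (any(c(tau_m, refractory, tau_syn) <= 0)) {
    abort("Time constants and refractory period must be > 0.")
  }
  structure(
    list(v_rest = v_rest, v_threshold = v_threshold, v_reset = v_reset,
         tau_m = tau_m, refractory = refractory, tau_syn = tau_syn),
    class = "lif_params"
  )
}

#' Mushroom-body network specification
#'
#' Five leaky integrate-and-fire units: projection neurons PN_X (pooling
#' the 8 OR22a inputs) and PN_Y (pooling the 23 OR59b inputs), a
#' feedforward inhibitory neuron I driven by both PNs, and two Kenyon
#' cells. Each PN excites one KC strongly and the other weakly
#' (PN_X -> KC_X strong, PN_X -> KC_Y weak; PN_Y -> KC_Y strong,
#' PN_Y -> KC_X weak); I inhibits both KCs. Synapses are current-based:
#' each presynaptic spike adds an exponentially decaying current of
#' amplitude `weight` (mV/ms, decay `tau_syn`) to the target after the
#' connection delay.
#'
#' Default weights come from the shipped calibration ([calibrate_weights()]):
#' ORN->PN weights scaled so a synchronous volley of the full pool drives a
#' PN spike within 2 ms of arrival; strong:weak PN->KC ratio 2.5 with the
#' weak synapse alone subthreshold; PN->I strong enough that I fires within
#' ~0.3 ms of PN drive; I->KC strong enough that inhibition triggered by
#' the leading PN keeps the lagging KC below threshold.
#'
#' @param w_or22a_pn,w_or59b_pn ORN -> PN synaptic amplitudes (mV/ms per
#'   spike), > 0.
#' @param w_pn_kc_strong,w_pn_kc_weak PN -> KC amplitudes, strong > weak > 0.
#' @param w_pn_i PN -> I amplitude, > 0.
#' @param w_i_kc I -> KC amplitude, <= 0.
#' @param delay_orn_pn,delay_pn_kc,delay_pn_i,delay_i_kc Connection delays,
#'   ms.
#' @param pn,kc,inh [lif_params()] per population.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(w_or22a_pn = 3.2, w_or59b_pn = 0.8,
                         w_pn_kc_strong = 33, w_pn_kc_weak = 13.2,
                         w_pn_i = 60, w_i_kc = -60,
                         delay_orn_pn = 1, delay_pn_kc = 1.5,
                         delay_pn_i = 1, delay_i_kc = 1,
                         pn = lif_params(), kc = lif_params(),
                         inh = lif_params(tau_m = 3)) {
  if (any(c(w_or22a_pn, w_or59b_pn, w_pn_kc_strong, w_pn_kc_weak, w_pn_i) <= 0)) {
    abort("Excitatory weights must be > 0.")
  }
  if (w_i_kc > 0) abort("Inhibitory weight `w_i_kc` must be <= 0.")
  if (w_pn_kc_strong <= w_pn_kc_weak) {
    abort("The strong PN->KC weight must strictly exceed the weak one.")
  }
  structure(
    list(w_or22a_pn = w_or22a_pn, w_or59b_pn = w_or59b_pn,
         w_pn_kc_strong = w_pn_kc_strong, w_pn_kc_weak = w_pn_kc_weak,
         w_pn_i = w_pn_i, w_i_kc = w_i_kc,
         delay_orn_pn = delay_orn_pn, delay_pn_kc = delay_pn_kc,
         delay_pn_i = delay_pn_i, delay_i_kc = delay_i_kc,
         pn = pn, kc = kc, inh = inh),
    class = "network_spec"
  )
}

#' @rdname network_spec
#' @export
default_network <- function() network_spec()

net_neurons <- c("PN_X", "PN_Y", "I", "KC_X", "KC_Y")

#' Simulate the rank-order mushroom-body network on one ORN input set
#'
#' Exponential-Euler integration of `dV/dt = -(V - v_rest)/tau_m + I_syn(t)`
#' on a fixed grid. Threshold crossing emits a spike, resets the membrane
#' and clamps it for the refractory period; emitted spikes schedule
#' synaptic-current increments on their targets after the connection delay.
#' The simulation is deterministic given the inputs.
#'
#' @param spec A [network_spec()].
#' @param orn_spikes Spike tibble of one run: by default exactly 8 distinct
#'   OR22a and 23 distinct OR59b trains (`strict = FALSE` lifts the count
#'   check). Spike times must lie within `span`.
#' @param dt Integration step, ms (must be <= 0.05; sub-millisecond timing
#'   is the object of study).
#' @param span Simulation span `(t0, t1)`, ms.
#' @param decision_window Window of KC first spikes used for
#'   classification, ms.
#' @param record_traces Keep membrane traces? (memory ~ 5 doubles/step).
#' @param strict Enforce the 8 + 23 ORN counts.
#' @return An object of class `lif_result`: list with `spikes` (tibble
#'   `neuron`, `time_ms`), `traces` (tibble `time_ms`, `neuron`, `v_mV`,
#'   or `NULL`), `classification`, `kc_first_spike` (ms or `NA`), `dt`,
#'   `span`, `decision_window`.
#' @export
simulate_network <- function(spec, orn_spikes, dt = 0.025, span = c(-10, 50),
                             decision_window = c(0, span[2]),
                             record_traces = FALSE, strict = TRUE) {
  stopifnot(inherits(spec, "network_spec"))
  if (dt > 0.05) abort("`dt` must be <= 0.05 ms.")
  orn_spikes <- validate_spikes(orn_spikes)
  if (any(orn_spikes$spike_time_ms < span[1] |
            orn_spikes$spike_time_ms > span[2])) {
    abort("ORN spike times outside the simulation span.")
  }
  counts <- orn_spikes |>
    dplyr::distinct(.data$receptor, .data$neuron_id, .data$trial) |>
    dplyr::count(.data$receptor)
  n22 <- counts$n[counts$receptor == "OR22a"]
  n59 <- counts$n[counts$receptor == "OR59b"]
  if (strict && !(length(n22) == 1 && n22 == 8 &&
                    length(n59) == 1 && n59 == 23)) {
    abort("Expected exactly 8 OR22a and 23 OR59b trains (use strict = FALSE to override).")
  }

  n_steps <- as.integer(ceiling((span[2] - span[1]) / dt))
  step_of <- function(t_arrival) {
    # increment lands on the first grid point at or after arrival
    # (tolerance absorbs floating-point error for on-grid arrivals)
    i <- ceiling((t_arrival - span[1]) / dt - 1e-9)
    pmax(as.integer(i), 1L)
  }
  delay_steps <- function(d) as.integer(round(d / dt))

  # input current increments (columns: PN_X, PN_Y, I, KC_X, KC_Y)
  inc <- matrix(0, nrow = n_steps + 1L, ncol = 5L)
  is22 <- orn_spikes$receptor == "OR22a"
  st22 <- step_of(orn_spikes$spike_time_ms[is22] + spec$delay_orn_pn)
  st59 <- step_of(orn_spikes$spike_time_ms[!is22] + spec$delay_orn_pn)
  for (s in st22) if (s <= n_steps) inc[s, 1] <- inc[s, 1] + spec$w_or22a_pn
  for (s in st59) if (s <= n_steps) inc[s, 2] <- inc[s, 2] + spec$w_or59b_pn

  pars <- list(spec$pn, spec$pn, spec$inh, spec$kc, spec$kc)
  v_rest <- vapply(pars, `[[`, numeric(1), "v_rest")
  v_th <- vapply(pars, `[[`, numeric(1), "v_threshold")
  v_reset <- vapply(pars, `[[`, numeric(1), "v_reset")
  tau_m <- vapply(pars, `[[`, numeric(1), "tau_m")
  tau_syn <- vapply(pars, `[[`, numeric(1), "tau_syn")
  ref_steps <- vapply(pars, function(p) {
    as.integer(round(p$refractory / dt))
  }, integer(1))
  decay_m <- exp(-dt / tau_m)
  decay_s <- exp(-dt / tau_syn)

  d_pk <- delay_steps(spec$delay_pn_kc)
  d_pi <- delay_steps(spec$delay_pn_i)
  d_ik <- delay_steps(spec$delay_i_kc)

  v <- v_rest
  s <- numeric(5)
  ref <- integer(5)
  times <- span[1] + dt * seq_len(n_steps)
  spike_rec <- vector("list", 5)
  traces <- if (record_traces) matrix(NA_real_, n_steps, 5) else NULL

  add_inc <- function(step, col, w) {
    if (step <= n_steps) inc[step, col] <<- inc[step, col] + w
  }

  for (i in seq_len(n_steps)) {
    s <- s * decay_s + inc[i, ]
    v_inf <- v_rest + tau_m * s
    v <- v_inf + (v - v_inf) * decay_m
    in_ref <- ref > 0L
    if (any(in_ref)) {
      v[in_ref] <- v_reset[in_ref]
      ref[in_ref] <- ref[in_ref] - 1L
    }
    fired <- which(v >= v_th & !in_ref)
    if (length(fired)) {
      for (j in fired) {
        spike_rec[[j]] <- c(spike_rec[[j]], times[i])
        v[j] <- v_reset[j]
        ref[j] <- ref_steps[j]
        if (j == 1L) { # PN_X
          add_inc(i + d_pk, 4L, spec$w_pn_kc_strong)
          add_inc(i + d_pk, 5L, spec$w_pn_kc_weak)
          add_inc(i + d_pi, 3L, spec$w_pn_i)
        } else if (j == 2L) { # PN_Y
          add_inc(i + d_pk, 5L, spec$w_pn_kc_strong)
          add_inc(i + d_pk, 4L, spec$w_pn_kc_weak)
          add_inc(i + d_pi, 3L, spec$w_pn_i)
        } else if (j == 3L) { # I
          add_inc(i + d_ik, 4L, spec$w_i_kc)
          add_inc(i + d_ik, 5L, spec$w_i_kc)
        }
      }
    }
    if (record_traces) traces[i, ] <- v
    if (any(!is.finite(v))) abort("Integration failure: non-finite membrane potential.")
  }

  spikes <- tibble(
    neuron = rep(net_neurons, lengths(spike_rec)),
    time_ms = unlist(spike_rec) %||% numeric(0)
  )
  trace_tbl <- NULL
  if (record_traces) {
    trace_tbl <- tibble(
      time_ms = rep(times, 5),
      neuron = rep(net_neurons, each = n_steps),
      v_mV = as.vector(traces)
    )
  }
  res <- structure(
    list(spikes = spikes, traces = trace_tbl, dt = dt, span = span,
         decision_window = decision_window),
    class = "lif_result"
  )
  cls <- classify_trial(res, decision_window)
  res$classification <- cls$label
  res$kc_first_spike <- cls$kc_first_spike
  res
}

#' Classify one simulated trial from its KC spikes
#'
#' Correct-by-construction rule: a first spike in KC_X only (within the
#' decision window) means methyl butyrate; in KC_Y only, ethyl acetate;
#' both or neither is `"invalid"`.
#'
#' @param result A `lif_result` from [simulate_network()].
#' @param decision_window Window of KC first spikes considered, ms.
#' @return A list with `label` and `kc_first_spike` (first spike time of
#'   the responding KC, ms; `NA` when invalid).
#' @export
classify_trial <- function(result, decision_window = result$decision_window) {
  first_in <- function(neuron) {
    t <- result$spikes$time_ms[result$spikes$neuron == neuron]
    t <- t[t >= decision_window[1] & t <= decision_window[2]]
    if (length(t)) min(t) else NA_real_
  }
  fx <- first_in("KC_X")
  fy <- first_in("KC_Y")
  if (!is.na(fx) && is.na(fy)) {
    list(label = "methyl butyrate", kc_first_spike = fx)
  } else if (is.na(fx) && !is.na(fy)) {
    list(label = "ethyl acetate", kc_first_spike = fy)
  } else {
    list(label = "invalid", kc_first_spike = NA_real_)
  }
}

#' @export
print.lif_result <- function(x, ...) {
  n <- table(factor(x$spikes$neuron, levels = net_neurons))
  cat("LIF network simulation (", x$span[1], "to", x$span[2], "ms, dt =",
      x$dt, "ms)\n")
  cat("Spikes:", paste(sprintf("%s=%d", names(n), n), collapse = ", "), "\n")
  cat("Classification:", x$classification,
      if (!is.na(x$kc_first_spike)) {
        sprintf("(KC first spike %.2f ms)", x$kc_first_spike)
      } else "", "\n")
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.lif_result <- function(object, ...) {
  sp <- dplyr::mutate(object$spikes,
                      neuron = factor(.data$neuron, levels = rev(net_neurons)))
  p <- ggplot(sp, aes(x = .data$time_ms, y = .data$neuron)) +
    geom_point(shape = "|", size = 4) +
    labs(x = "Time (ms)", y = NULL,
         title = sprintf("Classification: %s", object$classification)) +
    theme_minimal()
  if (!is.null(object$traces)) {
    p <- ggplot(object$traces, aes(x = .data$time_ms, y = .data$v_mV)) +
      geom_line() +
      facet_grid(
        rows = vars(factor(.data$neuron, levels = net_neurons))
      ) +
      geom_point(
        data = sp, aes(x = .data$time_ms, y = -40),
        inherit.aes = FALSE, shape = "|", size = 3
      ) +
      labs(x = "Time (ms)", y = "Membrane potential (mV)",
           title = sprintf("Classification: %s", object$classification)) +
      theme_minimal()
  }
  p
}
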