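#' Build a synthetic odorant stimulus pulse
#'
#' Emulates the fast odorant pulse delivered by a high-speed olfactory
#' stimulator, as measured with a photoionization detector: a smooth
#' sigmoidal rise to a concentration-dependent plateau, followed by a
#' mirrored fall after `duration`. The rise is a logistic whose steepness is
#' set so that the 5--95% span of the analytic curve equals
#' `rise_time_5_95` exactly; [rise_time_5_95()] applied to the sampled
#' waveform recovers it to well within one sample step.
#'
#' Time zero is odorant arrival, defined as the waveform's upward crossing
#' of 5% of the plateau, so `onset_time = 0` by construction and evoked
#' spike latencies are measured on the same clock.
#'
#' @param odorant Odorant label (e.g. `"methyl butyrate"`).
#' @param concentration log10 dilution (e.g. -4). Sets the plateau
#'   amplitude monotonically; the waveform is normalized so the plateau is
#'   at most 1.
#' @param rise_time_5_95 Requested 5--95% rise time in ms (stimulator
#'   default 3.6 ms).
#' @param duration Plateau duration in ms (5% up-crossing to 5% down-crossing).
#' @param dt Sample step in ms; must satisfy `dt <= rise_time_5_95 / 10`.
#' @param t_pre,t_post Padding before onset and after offset, ms.
#'
#' @return A tibble of class `orn_stimulus` with columns `time_ms` and
#'   `signal`, and attributes `odorant`, `concentration`, `onset_time`,
#'   `rise_time_5_95`, `duration`.
#' @examples
#' stim <- make_stimulus("methyl butyrate", -4)
#' rise_time_5_95(stim)
#' @export
make_stimulus <- function(odorant = "methyl butyrate", concentration = -4,
                          rise_time_5_95 = 3.6, duration = 500, dt = 0.05,
                          t_pre = 20, t_post = 20) {
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be a positive number of ms.")
  }
  if (!is.numeric(dt) || dt <= 0) {
    abort("`dt` must be a positive number of ms.")
  }
  if (rise_time_5_95 <= 0) {
    abort("`rise_time_5_95` must be > 0 ms.")
  }
  if (dt > rise_time_5_95 / 10) {
    abort("`dt` must be <= rise_time_5_95 / 10 to resolve the rise.")
  }

  # logistic with 5->95% span equal to the requested rise time;
  # t = 0 placed at the 5% crossing
  s <- rise_time_5_95 / (2 * log(19))
  t_mid <- rise_time_5_95 / 2
  amp <- stimulus_amplitude(concentration)

  t <- seq(-t_pre, duration + t_post, by = dt)
  y_rise <- 1 / (1 + exp(-(t - t_mid) / s))
  y_fall <- 1 / (1 + exp((t - duration - t_mid) / s))
  y <- amp * pmin(y_rise, y_fall)

  out <- tibble(time_ms = t, signal = y)
  structure(out,
    class = c("orn_stimulus", class(out)),
    odorant = odorant, concentration = concentration,
    onset_time = 0, rise_time_5_95 = rise_time_5_95, duration = duration
  )
}

# plateau amplitude: monotone in log10 dilution, 1 at the top of the
# calibrated range (10^-2), positive throughout
stimulus_amplitude <- function(concentration, range = c(-8, -2)) {
  a <- (concentration - range[1]) / (range[2] - range[1])
  pmin(pmax(a, 0.05), 1)
}

#' Measure the 5--95% rise time of a stimulus waveform
#'
#' Time between the first upward crossing of 5% and the first upward
#' crossing of 95% of the plateau level (taken as the waveform maximum),
#' with linear interpolation between samples.
#'
#' @param stim A waveform: either an `orn_stimulus` or any data frame with
#'   columns `time_ms` and `signal`.
#' @return Rise time in ms, or `NA` (with a warning) if the waveform never
#'   reaches 95% of its plateau.
#' @export
rise_time_5_95 <- function(stim) {
  stopifnot(all(c("time_ms", "signal") %in% names(stim)))
  t <- stim$time_ms
  y <- stim$signal
  plateau <- max(y)
  if (plateau <= 0) {
    warn("Waveform has no positive plateau; rise time undefined.")
    return(NA_real_)
  }
  t5 <- first_upcross(t, y, 0.05 * plateau)
  t95 <- first_upcross(t, y, 0.95 * plateau)
  if (is.na(t5) || is.na(t95)) {
    warn("Waveform does not reach 95% of its plateau; rise time undefined.")
    return(NA_real_)
  }
  t95 - t5
}

# first upward crossing of `level`, linearly interpolated
first_upcross <- function(t, y, level) {
  above <- y >= level
  if (above[1]) return(t[1])
  i <- which(!above[-length(above)] & above[-1])
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  if (y[i + 1] == y[i]) return(t[i + 1])
  t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}

#' @exportS3Method ggplot2::autoplot
autoplot.orn_stimulus <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ms, y = .data$signal)) +
    geom_line() +
    geom_vline(xintercept = attr(object, "onset_time"), linetype = "dashed") +
    labs(
      x = "Time (ms)", y = "Normalized signal",
      title = sprintf(
        "%s, 10^%g (5-95%% rise %.1f ms)",
        attr(object, "odorant"), attr(object, "concentration"),
        attr(object, "rise_time_5_95")
      )
    ) +
    theme_minimal()
}
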