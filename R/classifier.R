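#' Latency and ISI differences between receptor-type populations
#'
#' For each (odorant, concentration) condition and each random draw:
#' sample a pool of OR59b and a pool of OR22a (neuron, trial) picks
#' (neurons with replacement, one random trial each); the population
#' latency of each type is the earliest first-spike latency across its
#' pool (the first spike a downstream neuron could see); the population
#' ISI is the median first-to-second interval across the pool. Differences
#' use the fixed sign convention OR22a minus OR59b, so positive
#' `delta_latency` means OR59b led.
#'
#' @param spikes A spike tibble containing both receptor types.
#' @param n_draws Random pool draws per condition.
#' @param n_or59b,n_or22a Pool sizes (anatomical defaults 23 and 8).
#' @param response_window Response window, ms.
#' @param seed Integer seed (required).
#' @return A tibble with columns `odorant`, `concentration`, `draw`,
#'   `delta_latency`, `delta_isi` (ms; `NA` when a type had no evoked
#'   spike in the draw).
#' @export
latency_differences <- function(spikes, n_draws = 100, n_or59b = 23,
                                n_or22a = 8, response_window = c(0, 200),
                                seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic operations take an explicit seed.")
  }
  spikes <- validate_spikes(spikes)
  if (!all(known_receptors %in% unique(spikes$receptor))) {
    abort("Both receptor types (OR59b, OR22a) must be present.")
  }

  lat <- latency_table(spikes, response_window)
  isi <- spikes |>
    dplyr::group_by(.data$receptor, .data$odorant, .data$concentration,
                    .data$neuron_id, .data$trial) |>
    dplyr::summarise(
      isi_ms = {
        t <- sort(.data$spike_time_ms)
        t <- t[t >= response_window[1] & t <= response_window[2]]
        if (length(t) >= 2) t[2] - t[1] else NA_real_
      },
      .groups = "drop"
    )
  feats <- dplyr::left_join(
    lat, isi,
    by = c("receptor", "odorant", "concentration", "neuron_id", "trial")
  )

  conds <- dplyr::distinct(feats, .data$odorant, .data$concentration)
  with_seed(as.integer(seed), {
    out <- purrr::pmap(conds, function(odorant, concentration) {
      sub <- feats[feats$odorant == odorant &
                     feats$concentration == concentration, ]
      pools <- lapply(c(OR59b = "OR59b", OR22a = "OR22a"), function(rec) {
        s <- sub[sub$receptor == rec, ]
        if (nrow(s) == 0) {
          abort(sprintf("No %s trains at odorant '%s', concentration %g.",
                        rec, odorant, concentration))
        }
        list(trials_by_neuron = split(seq_len(nrow(s)), s$neuron_id), tab = s)
      })
      draw_type <- function(pool, size) {
        ns <- sample(names(pool$trials_by_neuron), size, replace = TRUE)
        rows <- vapply(ns, function(n) {
          ii <- pool$trials_by_neuron[[n]]
          ii[sample.int(length(ii), 1)]
        }, integer(1))
        picked <- pool$tab[rows, ]
        lat_ok <- picked$latency_ms[!is.na(picked$latency_ms)]
        isi_ok <- picked$isi_ms[!is.na(picked$isi_ms)]
        c(
          lat = if (length(lat_ok)) min(lat_ok) else NA_real_,
          isi = if (length(isi_ok)) median(isi_ok) else NA_real_
        )
      }
      res <- vapply(seq_len(n_draws), function(d) {
        a <- draw_type(pools$OR59b, n_or59b)
        b <- draw_type(pools$OR22a, n_or22a)
        c(b[["lat"]] - a[["lat"]], b[["isi"]] - a[["isi"]])
      }, numeric(2))
      tibble(
        odorant = odorant, concentration = concentration,
        draw = seq_len(n_draws),
        delta_latency = res[1, ], delta_isi = res[2, ]
      )
    })
    purrr::list_rbind(out)
  })
}

#' Classify an odorant from a latency or ISI difference
#'
#' A difference (OR22a minus OR59b) strictly greater than the threshold
#' means OR59b led, i.e. ethyl acetate; otherwise methyl butyrate. A
#' difference exactly at the threshold is methyl butyrate (strict
#' inequality). Undefined differences yield `"abstain"`.
#'
#' @param delta Numeric difference(s), ms (OR22a - OR59b).
#' @param threshold Classification threshold, ms. The single threshold
#'   0.76 ms (latency) or 0.77 ms (ISI) separates the two odorants across
#'   four to five orders of magnitude in concentration.
#' @return Character vector of labels (`"ethyl acetate"`,
#'   `"methyl butyrate"` or `"abstain"`).
#' @examples
#' classify_odorant(c(2, -1, NA), threshold = 0.76)
#' @export
classify_odorant <- function(delta, threshold = 0.76) {
  dplyr::case_when(
    is.na(delta) ~ "abstain",
    delta > threshold ~ "ethyl acetate",
    .default = "methyl butyrate"
  )
}

#' Classification accuracy per condition
#'
#' Percentage of draws whose predicted label matches the generating
#' odorant, per (odorant, concentration). Abstentions (undefined
#' differences) count as incorrect.
#'
#' @param samples Output of [latency_differences()].
#' @param threshold Threshold in ms.
#' @param feature `"latency"` (uses `delta_latency`) or `"isi"`
#'   (`delta_isi`).
#' @return A tibble with columns `odorant`, `concentration`,
#'   `accuracy_pct`, `n_draws`, `n_abstain`.
#' @export
classification_accuracy <- function(samples, threshold = 0.76,
                                    feature = c("latency", "isi")) {
  feature <- match.arg(feature)
  delta <- if (feature == "latency") samples$delta_latency else samples$delta_isi
  samples |>
    dplyr::mutate(.pred = classify_odorant(delta, threshold)) |>
    dplyr::group_by(.data$odorant, .data$concentration) |>
    dplyr::summarise(
      accuracy_pct = 100 * mean(.data$.pred == .data$odorant),
      n_draws = dplyr::n(),
      n_abstain = sum(.data$.pred == "abstain"),
      .groups = "drop"
    )
}

#' Fit the single classification threshold
#'
#' Exhaustive scan for the threshold maximizing pooled accuracy across all
#' concentrations simultaneously (both odorants, abstentions counted as
#' errors). Accuracy as a function of the threshold is piecewise constant,
#' changing only at observed difference values; the scan evaluates every
#' such interval and ties are broken toward the midpoint of the widest
#' optimal interval.
#'
#' @inheritParams classification_accuracy
#' @return An object of class `odor_threshold` with elements `threshold`,
#'   `feature`, `accuracy_pct` (pooled, at the fitted threshold),
#'   `interval` (the optimal threshold interval), `n` and `by_condition`
#'   (per-condition accuracy at the fitted threshold). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_threshold <- function(samples, feature = c("latency", "isi")) {
  feature <- match.arg(feature)
  if (length(unique(samples$odorant)) < 2) {
    abort("Both odorant classes must be represented to fit a threshold.")
  }
  delta <- if (feature == "latency") samples$delta_latency else samples$delta_isi
  truth <- samples$odorant
  ok <- !is.na(delta)
  d <- sort(unique(delta[ok]))
  if (length(d) == 0) abort("No defined difference samples.")

  # candidate thresholds: one per constant-accuracy interval
  # (-Inf, d1), [d1, d2), ..., [dk, Inf); strict `> thr` rule
  lo <- c(d[1] - 1, d)
  hi <- c(d, d[length(d)] + 1)
  cand <- (lo + hi) / 2
  cand[1] <- d[1] - 1
  acc <- vapply(cand, function(th) {
    mean(classify_odorant(delta, th) == truth)
  }, numeric(1))
  best <- max(acc)
  ib <- which(acc == best)
  # widest optimal interval, midpoint tie-break
  widths <- hi[ib] - lo[ib]
  pick <- ib[which.max(widths)]
  thr <- (lo[pick] + hi[pick]) / 2

  structure(
    list(
      threshold = thr, feature = feature, accuracy_pct = 100 * best,
      interval = c(lo[pick], hi[pick]), n = length(delta),
      by_condition = classification_accuracy(samples, thr, feature)
    ),
    class = "odor_threshold"
  )
}

#' @export
print.odor_threshold <- function(x, ...) {
  cat(sprintf(
    "Odorant classification threshold (%s): %.3f ms\n", x$feature, x$threshold
  ))
  cat(sprintf("Pooled accuracy: %.1f%% over %d draws\n", x$accuracy_pct, x$n))
  cat(sprintf("Optimal interval: [%.3f, %.3f) ms\n",
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.odor_threshold <- function(x, ...) {
  x$by_condition
}

#' @exportS3Method generics::glance
glance.odor_threshold <- function(x, ...) {
  tibble(
    threshold = x$threshold, feature = x$feature,
    accuracy_pct = x$accuracy_pct, n = x$n,
    interval_lo = x$interval[1], interval_hi = x$interval[2]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.odor_threshold <- function(object, ...) {
  ggplot(object$by_condition, aes(
    x = .data$concentration, y = .data$accuracy_pct,
    colour = .data$odorant, group = .data$odorant
  )) +
    geom_hline(yintercept = 50, linetype = "dashed") +
    geom_line() +
    geom_point() +
    labs(
      x = "Concentration (log10 dilution)", y = "Correct classification (%)",
      colour = NULL,
      title = sprintf("Single %s threshold: %.2f ms",
                      object$feature, object$threshold)
    ) +
    ylim(0, 100) +
    theme_minimal()
}
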