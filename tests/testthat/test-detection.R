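test_that("d_a matches hand-computed values and edge conventions", {
  expect_equal(detection_accuracy(c(2, 3, 4), c(0, 1, 2)), 2)
  expect_equal(detection_accuracy(c(0, 1, 2), c(0, 1, 2)), 0)
  # mean gap 5 with SDs 3 and 4: 5 / sqrt(25/2)
  expect_equal(detection_accuracy(c(2, 5, 8), c(-4, 0, 4)),
               5 / sqrt(25 / 2), tolerance = 1e-9)
  expect_equal(detection_accuracy(c(3, 3), c(3, 3)), 0)
  expect_identical(detection_accuracy(c(4, 4), c(1, 1)), Inf)
  expect_error(detection_accuracy(c(1), c(0, 1)), "at least 2")
})

test_that("d_a is shift-invariant and scales reciprocally", {
  e <- c(2, 5, 9, 4)
  s <- c(0, 1, 3, 2)
  d0 <- detection_accuracy(e, s)
  expect_equal(detection_accuracy(e + 7, s + 7), d0, tolerance = 1e-12)
  expect_equal(detection_accuracy(e / 3, s / 3), d0, tolerance = 1e-12)
})

test_that("the Gaussian observer maps d_a to a false-positive rate", {
  expect_lt(false_positive_rate(5), 0.01)
  expect_equal(false_positive_rate(5), pnorm(-2.5), tolerance = 1e-12)
  expect_equal(false_positive_rate(0), 0.5)
  expect_equal(false_positive_rate(2), pnorm(-1), tolerance = 1e-12)
  expect_error(false_positive_rate(-1), "non-negative")
})

test_that("pooled counts follow the window and tiling conventions", {
  spk <- spike_rows("n1", c(-150, -80, 5, 6))
  picks <- tibble::tibble(neuron_id = "n1", trial = 1L)
  pc <- pooled_counts(spk, picks, 5, 2, baseline_window = c(-200, 0))
  expect_equal(pc$evoked, 2) # [5, 7) holds both spikes
  expect_equal(sum(pc$spont_counts), 2)
  expect_equal(length(pc$spont_counts), 100)

  # additivity: counts of a merged pool equal the sum over sub-pools
  spk2 <- dplyr::bind_rows(spk, spike_rows("n2", c(5.5, 20)))
  p1 <- pooled_counts(spk2, picks, 5, 2)
  p2 <- pooled_counts(spk2, tibble::tibble(neuron_id = "n2", trial = 1L), 5, 2)
  pu <- pooled_counts(spk2, tibble::tibble(neuron_id = c("n1", "n2"),
                                           trial = 1L), 5, 2)
  expect_equal(pu$evoked, p1$evoked + p2$evoked)
  expect_equal(pu$spont_counts, p1$spont_counts + p2$spont_counts)

  # empty baseline -> all-zero spontaneous counts
  quiet <- spike_rows("n1", c(5, 6))
  expect_true(all(pooled_counts(quiet, picks, 5, 2)$spont_counts == 0))
  expect_error(pooled_counts(spk, picks, 5, 50, baseline_window = c(-20, 0)),
               "Baseline")
})

test_that("pooled counts and d_a agree with a naive oracle on small instances", {
  for (s in 1:3) {
    spk <- random_spike_table(100 + s, n_neurons = 5, n_trials = 3,
                              n_spikes = 8, t_range = c(-100, 50))
    picks <- tibble::tibble(neuron_id = c("n1", "n3", "n3"),
                            trial = c(1L, 2L, 3L))
    it <- 4
    ws <- 3
    pc <- pooled_counts(spk, picks, ws, it, baseline_window = c(-100, 0))
    # naive recomputation straight off the table
    naive_count <- function(lo, hi) {
      sum(vapply(seq_len(nrow(picks)), function(k) {
        tt <- spk$spike_time_ms[spk$neuron_id == picks$neuron_id[k] &
                                  spk$trial == picks$trial[k]]
        sum(tt >= lo & tt < hi)
      }, numeric(1)))
    }
    expect_equal(pc$evoked, naive_count(ws, ws + it))
    tile_lo <- seq(-100, -it, by = it)
    expect_equal(pc$spont_counts,
                 vapply(tile_lo, function(lo) naive_count(lo, lo + it),
                        numeric(1)))
    # d_a downstream of the counts equals the direct formula
    ev <- pc$spont_counts + 2
    expect_equal(
      detection_accuracy(ev, pc$spont_counts),
      2 / sqrt((var(ev) + var(pc$spont_counts)) / 2)
    )
  }
})

test_that("peak d_a grows with pool size and integration time on evoked data", {
  spk <- generate_population("OR59b", "methyl butyrate", -3,
    n_neurons = 8, n_trials = 6, seed = 31, baseline = 200, duration = 80
  )
  mean_peak <- function(ps, it) {
    pd <- peak_detection_accuracy(spk, ps, it, n_pools = 30, n_reps = 4,
                                  window_starts = seq(0, 25, 1), seed = 5)
    mean(pd$peak_da)
  }
  expect_gte(mean_peak(23, 2), mean_peak(1, 2))
  expect_gte(mean_peak(23, 8), mean_peak(23, 2))
})

test_that("spontaneous-only data yields near-zero peak d_a and no detection", {
  spont <- withr::with_seed(13, {
    dplyr::bind_rows(lapply(1:6, function(i) {
      dplyr::bind_rows(lapply(1:4, function(j) {
        spike_rows(sprintf("n%d", i),
                   sort(stats::runif(8, -200, 50)), trial = j)
      }))
    }))
  })
  pd <- peak_detection_accuracy(spont, 10, 4, n_pools = 30, n_reps = 4,
                                window_starts = seq(0, 30, 2), seed = 17)
  expect_lt(mean(pd$peak_da), 2)
  mit <- min_integration_time(spont, 10, threshold = 5, grid = c(1, 4, 16),
                              n_pools = 20, n_repetitions = 5,
                              window_starts = seq(0, 30, 2), seed = 19)
  expect_true(all(is.na(mit$min_integration_time)))
})

test_that("minimum integration time honours the threshold rule", {
  spk <- generate_population("OR59b", "methyl butyrate", -3,
    n_neurons = 6, n_trials = 5, seed = 23, baseline = 100, duration = 60
  )
  # threshold 0 is exceeded by the smallest grid value in every repetition
  mit0 <- min_integration_time(spk, 8, threshold = 0, grid = c(2, 5, 10),
                               n_pools = 15, n_repetitions = 4,
                               window_starts = seq(0, 20, 1), seed = 29)
  expect_true(all(mit0$min_integration_time == 2))
})
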