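test_that("the threshold rule and its conventions classify single deltas", {
  expect_equal(classify_odorant(2, 0.76), "ethyl acetate")
  expect_equal(classify_odorant(0.76, 0.76), "methyl butyrate") # tie -> MB
  expect_equal(classify_odorant(-1, 0.76), "methyl butyrate")
  expect_equal(classify_odorant(NA_real_, 0.76), "abstain")
})

test_that("latency differences carry the OR22a-minus-OR59b sign convention", {
  spk <- dplyr::bind_rows(
    spike_rows("b1", 4.0, receptor = "OR59b"),
    spike_rows("a1", 6.0, receptor = "OR22a")
  )
  samp <- latency_differences(spk, n_draws = 5, seed = 1)
  expect_true(all(samp$delta_latency == 2.0))
  # identical populations -> delta centered at zero
  spk2 <- dplyr::bind_rows(
    spike_rows(sprintf("b%d", 1:3), c(5, 6, 7), receptor = "OR59b"),
    spike_rows(sprintf("a%d", 1:3), c(5, 6, 7), receptor = "OR22a")
  )
  samp2 <- latency_differences(spk2, n_draws = 300, seed = 2,
                               n_or59b = 3, n_or22a = 3)
  expect_lt(abs(mean(samp2$delta_latency)), 0.3)
})

test_that("the generator's ethyl acetate rank offset is recovered as ~+3 ms", {
  spk <- dplyr::bind_rows(
    generate_population("OR59b", "ethyl acetate", -2, 10, 8, seed = 61,
                        baseline = 20, duration = 60, spont_rate = 0),
    generate_population("OR22a", "ethyl acetate", -2, 8, 8, seed = 62,
                        baseline = 20, duration = 60, spont_rate = 0)
  )
  samp <- latency_differences(spk, n_draws = 100, seed = 63)
  # documented offset 3 ms, plus a small earliest-of-pool order-statistic bias
  expect_equal(mean(samp$delta_latency), 3, tolerance = 0.25)
})

test_that("accuracy counts abstentions as errors and hits the degenerate limits", {
  samples <- tibble::tibble(
    odorant = rep(c("ethyl acetate", "methyl butyrate"), each = 4),
    concentration = -3, draw = 1:8,
    delta_latency = c(3, 3.5, 2.8, NA, -1, -0.5, -1.2, -2),
    delta_isi = 0
  )
  acc <- classification_accuracy(samples, threshold = 0.76)
  expect_equal(acc$accuracy_pct[acc$odorant == "ethyl acetate"], 75) # 1 abstain
  expect_equal(acc$accuracy_pct[acc$odorant == "methyl butyrate"], 100)
  expect_equal(acc$n_abstain, c(1L, 0L))

  # threshold at +Inf: everything labelled methyl butyrate
  acc_inf <- classification_accuracy(dplyr::filter(samples, !is.na(delta_latency)),
                                     threshold = Inf)
  expect_equal(acc_inf$accuracy_pct, c(0, 100))

  # symmetric random deltas about 0 at threshold 0: chance level
  sym <- withr::with_seed(5, tibble::tibble(
    odorant = sample(c("ethyl acetate", "methyl butyrate"), 2000, TRUE),
    concentration = -3, draw = 1:2000,
    delta_latency = stats::rnorm(2000), delta_isi = 0
  ))
  acc_sym <- classification_accuracy(sym, threshold = 0)
  expect_equal(mean(acc_sym$accuracy_pct), 50, tolerance = 5)
})

test_that("fit_threshold finds the documented optimum on separable clusters", {
  samples <- tibble::tibble(
    odorant = rep(c("ethyl acetate", "methyl butyrate"), each = 3),
    concentration = rep(c(-5, -3, -2), 2), draw = 1:6,
    delta_latency = c(3, 3, 3, -1, -1, -1), delta_isi = c(2, 2, 2, 0, 0, 0)
  )
  fit <- fit_threshold(samples, "latency")
  expect_equal(fit$threshold, 1.0) # midpoint of (-1, 3)
  expect_equal(fit$accuracy_pct, 100)

  # single sample per class: midpoint of the two deltas
  fit1 <- fit_threshold(samples[c(1, 4), ], "latency")
  expect_equal(fit1$threshold, 1.0)

  # identical overlapping clusters: 50% at the fitted threshold
  same <- dplyr::mutate(samples, delta_latency = 1)
  expect_equal(fit_threshold(same, "latency")$accuracy_pct, 50)
})

test_that("the fitted threshold is optimal over an exhaustive scan oracle", {
  for (s in 1:3) {
    samples <- withr::with_seed(300 + s, tibble::tibble(
      odorant = rep(c("ethyl acetate", "methyl butyrate"), each = 30),
      concentration = -3, draw = 1:60,
      delta_latency = c(stats::rnorm(30, 1.5, 1.2), stats::rnorm(30, -0.5, 1.2)),
      delta_isi = 0
    ))
    fit <- fit_threshold(samples, "latency")
    # oracle: dense grid scan of pooled accuracy
    grid <- seq(-6, 6, by = 0.005)
    oracle <- vapply(grid, function(th) {
      mean(classify_odorant(samples$delta_latency, th) == samples$odorant)
    }, numeric(1))
    expect_equal(fit$accuracy_pct / 100, max(oracle), tolerance = 1e-9)
    # never worse than threshold zero
    at0 <- mean(classify_odorant(samples$delta_latency, 0) == samples$odorant)
    expect_gte(fit$accuracy_pct / 100, at0)
  }
})

test_that("accuracy is invariant to a common latency shift of both types", {
  spk <- dplyr::bind_rows(
    generate_population("OR59b", "methyl butyrate", -3, 5, 4, seed = 71,
                        baseline = 10, duration = 60, spont_rate = 0),
    generate_population("OR22a", "methyl butyrate", -3, 5, 4, seed = 72,
                        baseline = 10, duration = 60, spont_rate = 0)
  )
  shifted <- dplyr::mutate(spk, spike_time_ms = spike_time_ms + 5)
  s1 <- latency_differences(spk, n_draws = 40, seed = 73)
  s2 <- latency_differences(shifted, n_draws = 40, seed = 73)
  expect_equal(s2$delta_latency, s1$delta_latency, tolerance = 1e-9)
})

test_that("tidiers expose the fit", {
  samples <- tibble::tibble(
    odorant = rep(c("ethyl acetate", "methyl butyrate"), each = 3),
    concentration = rep(c(-5, -3, -2), 2), draw = 1:6,
    delta_latency = c(3, 3, 3, -1, -1, -1), delta_isi = c(2, 2, 2, 0, 0, 0)
  )
  fit <- fit_threshold(samples, "latency")
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$threshold, 1.0)
  expect_equal(nrow(g), 1)
})
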