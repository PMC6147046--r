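test_that("a silent input leaves the network silent at rest", {
  empty <- spike_rows("x", numeric(0))
  res <- simulate_network(default_network(), empty, span = c(-5, 20),
                          record_traces = TRUE, strict = FALSE)
  expect_equal(nrow(res$spikes), 0)
  expect_true(all(res$traces$v_mV == -60))
  expect_equal(res$classification, "invalid")
})

test_that("a subthreshold input reproduces the closed-form PSP amplitude", {
  spec <- network_spec(w_or22a_pn = 4) # 8 x 4 = 32 mV/ms volley, still < gap?
  # single OR22a spike: amplitude 4, double-exponential PSP peak
  one <- spike_rows("a1", 0, receptor = "OR22a")
  res <- simulate_network(spec, one, span = c(-5, 30), record_traces = TRUE,
                          strict = FALSE)
  vx <- res$traces$v_mV[res$traces$neuron == "PN_X"]
  tm <- 5; ts <- 2
  tpk <- log(tm / ts) * tm * ts / (tm - ts)
  peak <- 4 * ts * tm / (tm - ts) * (exp(-tpk / tm) - exp(-tpk / ts))
  expect_equal(max(vx) - (-60), peak, tolerance = 0.02)
  expect_equal(nrow(res$spikes), 0) # stays subthreshold
})

test_that("rank order of the ORN volleys decides which KC fires", {
  spec <- default_network()
  mb <- simulate_network(spec, volley_input(t22 = 5, t59 = 7))
  expect_equal(mb$classification, "methyl butyrate")
  ea <- simulate_network(spec, volley_input(t22 = 7, t59 = 5))
  expect_equal(ea$classification, "ethyl acetate")
  # the winning KC fires, the other is held down by feedforward inhibition
  expect_true("KC_X" %in% mb$spikes$neuron)
  expect_false("KC_Y" %in% mb$spikes$neuron)
})

test_that("classify_trial implements the KC exclusivity rule", {
  fake <- function(kx, ky) {
    structure(list(
      spikes = tibble::tibble(
        neuron = c(rep("KC_X", length(kx)), rep("KC_Y", length(ky))),
        time_ms = c(kx, ky)
      ),
      decision_window = c(0, 50)
    ), class = "lif_result")
  }
  expect_equal(classify_trial(fake(12, numeric(0)))$label, "methyl butyrate")
  expect_equal(classify_trial(fake(numeric(0), 9))$label, "ethyl acetate")
  expect_equal(classify_trial(fake(12, 13))$label, "invalid")
  expect_equal(classify_trial(fake(numeric(0), numeric(0)))$label, "invalid")
  expect_equal(classify_trial(fake(12, numeric(0)))$kc_first_spike, 12)
})

test_that("removing feedforward inhibition abolishes KC exclusivity", {
  abl <- network_spec(w_i_kc = 0)
  res <- simulate_network(abl, volley_input(t22 = 5, t59 = 7))
  expect_true(all(c("KC_X", "KC_Y") %in% res$spikes$neuron))
  expect_equal(res$classification, "invalid")
})

test_that("translating all inputs shifts all output spikes exactly", {
  inp <- make_orn_input("methyl butyrate", -3, seed = 7)
  shifted <- dplyr::mutate(inp, spike_time_ms = spike_time_ms + 0.5)
  a <- simulate_network(default_network(), inp)
  b <- simulate_network(default_network(), shifted)
  expect_equal(b$spikes$time_ms, a$spikes$time_ms + 0.5, tolerance = 1e-9)
  expect_equal(b$classification, a$classification)
})

test_that("halving the integration step changes KC latencies by < 0.05 ms", {
  inp <- make_orn_input("methyl butyrate", -3, seed = 7)
  r1 <- simulate_network(default_network(), inp, dt = 0.025)
  r2 <- simulate_network(default_network(), inp, dt = 0.0125)
  expect_lt(abs(r1$kc_first_spike - r2$kc_first_spike), 0.05)
  expect_equal(r1$classification, r2$classification)
})

test_that("input validation catches bad simulations", {
  inp <- volley_input(5, 7)
  expect_error(simulate_network(default_network(), inp, dt = 0.1), "dt")
  late <- spike_rows("a1", 500, receptor = "OR22a")
  expect_error(simulate_network(default_network(), late, strict = FALSE),
               "span")
  expect_error(simulate_network(default_network(), inp[1:10, ]), "23 OR59b")
  expect_error(network_spec(w_pn_kc_strong = 5, w_pn_kc_weak = 6), "strong")
  expect_error(network_spec(w_i_kc = 2), "w_i_kc")
  expect_error(lif_params(v_rest = -60, v_threshold = -70), "v_reset")
})

test_that("classification is reliable per odorant and summarized by glance", {
  cr <- classification_rate(n_runs = 25, seed = 42)
  g <- glance(cr)
  expect_equal(nrow(g), 2)
  expect_true(all(g$rate_pct >= 78))
  expect_true(all(g$kc_latency_max <= 28))
  # determinism: same seed reproduces the runs
  cr2 <- classification_rate(n_runs = 25, seed = 42)
  expect_identical(tidy(cr), tidy(cr2))
})

test_that("time shifts that reverse the rank order collapse classification", {
  sw <- time_shift_sweep(shifts = c(-2, 0, 3), n_runs = 10, seed = 11)
  r <- function(sh) sw$rate_pct[sw$shift_ms == sh]
  # advancing OR22a (negative shift) preserves its lead; +3 ms reverses it
  expect_gte(r(-2), r(0) - 10)
  expect_lt(r(3), r(0))
  expect_lt(r(3), 50)
})
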