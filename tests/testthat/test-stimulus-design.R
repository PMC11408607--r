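test_that("air-dilution arithmetic reproduces the stimulator flows", {
  d <- compute_air_dilution(flow_config())
  expect_equal(d$total_flow, 2.1)
  expect_equal(signif(d$dilution_fraction, 3), 1.43e-3)

  # single-channel variant by hand: (3/300) * 300/1800 = 3/1800
  d1 <- compute_air_dilution(flow_config(n_channels = 1))
  expect_equal(d1$dilution_fraction, 3 / 1800)

  expect_equal(compute_air_dilution(
    flow_config(odorant_flow = 0))$dilution_fraction, 0)
})

test_that("Poisson valve sequences are seeded, truncated, exponential", {
  expect_identical(poisson_valve_sequence(10, 0.05, seed = 42),
                   poisson_valve_sequence(10, 0.05, seed = 42))
  expect_length(poisson_valve_sequence(0, 0.05, seed = 1)$toggle_times, 0)
  expect_error(poisson_valve_sequence(10, 0, seed = 1), "positive")

  # Poisson count law: expected 200 toggles per 10-s sequence at 50 ms
  counts <- vapply(1:300, function(s) {
    length(poisson_valve_sequence(10, 0.05, seed = s)$toggle_times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 200), 2 * sqrt(200 / 300) + 2 * sqrt(200) / sqrt(300))
  # inter-toggle intervals follow the exponential law
  iv <- unlist(lapply(1:50, function(s) {
    diff(poisson_valve_sequence(10, 0.05, seed = s)$toggle_times)
  }))
  expect_gt(stats::ks.test(iv, stats::pexp, rate = 20)$p.value, 0.01)
})

test_that("valve state bookkeeping is exact", {
  vs <- valve_sequence(c(0.1, 0.3, 0.5), duration = 1)
  expect_identical(valve_state(vs, c(0, 0.1, 0.2, 0.3, 0.4, 0.6)),
                   c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(valve_open_time(vs), 0.2 + 0.5)
  expect_error(valve_sequence(c(0.3, 0.1), duration = 1), "increasing")
  expect_error(valve_sequence(1.5, duration = 1), "duration")
})

test_that("pulse and asynchrony protocols open valves as designed", {
  p <- make_pulse_protocol("A", 0.5, "low")
  t0 <- p$t_origin
  expect_true(valve_state(p$channels$A, t0 + 0.25))
  expect_false(valve_state(p$channels$A, t0 + 0.51))
  expect_equal(valve_open_time(p$channels$B), 0)
  expect_error(make_pulse_protocol("A", 0), "positive")

  a96b <- make_asynchrony_protocol(96, "A", 0.5, "low")
  expect_equal(a96b$onset_asynchrony_ms, 96)
  expect_equal(a96b$channels$A$toggle_times[1], a96b$t_origin)
  expect_equal(a96b$channels$B$toggle_times[1], a96b$t_origin + 0.096)
  expect_equal(a96b$label, "A96B")

  b24a <- make_asynchrony_protocol(24, "B", 0.5, "low")
  expect_equal(b24a$onset_asynchrony_ms, -24)
  expect_equal(b24a$channels$B$toggle_times[1], b24a$t_origin)
  expect_equal(b24a$channels$A$toggle_times[2], b24a$t_origin + 0.024 + 0.5)

  # zero shift has no leader: both constructions coincide
  s1 <- make_asynchrony_protocol(0, "A", 0.5, "low")
  s2 <- make_asynchrony_protocol(0, "B", 0.5, "low")
  expect_equal(s1$channels$A$toggle_times, s2$channels$A$toggle_times)
  expect_equal(s1$channels$B$toggle_times, s2$channels$B$toggle_times)
  expect_error(make_asynchrony_protocol(-3, "A"), "non-negative")
})

test_that("background-pulse protocols give the background a sustained lead", {
  p <- make_background_pulse_protocol("B", "A", 2.0, 0.5, "high")
  expect_equal(p$label, "A on B")
  # background opens 2 s before the pulse-valve origin
  expect_equal(p$channels$B$toggle_times[1], p$t_origin - 2.0)
  expect_true(valve_state(p$channels$B, p$t_origin + 0.1))
  expect_equal(p$channels$A$toggle_times[1], p$t_origin)
  expect_error(make_background_pulse_protocol("B", "A", 1.0), ">= 2")
})

test_that("fluctuating mixture set shares exactly two base sequences", {
  set <- make_fluctuating_mixture_set(10, 0.05, seedA = 1, seedB = 2,
                                      level = "high")
  expect_named(set, c("A", "B", "AB_i", "AB_A", "AB_B"))
  # correlated mixture: both channels sample-identical
  expect_equal(set$AB_A$channels$A$toggle_times,
               set$AB_A$channels$B$toggle_times)
  expect_equal(set$AB_B$channels$A$toggle_times,
               set$AB_B$channels$B$toggle_times)
  # uncorrelated mixture reuses the single-odorant sequences
  expect_equal(set$AB_i$channels$A$toggle_times,
               set$A$channels$A$toggle_times)
  expect_equal(set$AB_i$channels$B$toggle_times,
               set$B$channels$B$toggle_times)
  # total odorant delivery matched across modes
  open_total <- vapply(set[c("AB_i", "AB_A", "AB_B")], function(p) {
    valve_open_time(p$channels$A) + valve_open_time(p$channels$B)
  }, numeric(1))
  expect_equal(unname(open_total[2]),
               2 * valve_open_time(set$A$channels$A))
  expect_equal(unname(open_total[3]),
               2 * valve_open_time(set$B$channels$B))
  expect_equal(unname(open_total[1]),
               valve_open_time(set$A$channels$A) +
                 valve_open_time(set$B$channels$B))
  expect_error(make_fluctuating_mixture_set(10, 0.05, 7, 7), "differ")
})

test_that("valve-to-concentration is a causal bounded first-order response", {
  # all-closed sequence: identically zero
  z <- valve_to_concentration(valve_sequence(numeric(), duration = 1), 0.5)
  expect_true(all(z$values == 0))

  # step response: (1 - e^-1) * peak at t = tau_rise
  vs <- valve_sequence(0, duration = 2)
  tr <- valve_to_concentration(vs, peak_conc = 1, tau_rise = 0.02,
                               tau_fall = 0.04, sampling_rate = 1000)
  expect_equal(tr$values[0.02 * 1000 + 1], 1 - exp(-1), tolerance = 1e-3)
  expect_true(all(tr$values <= 1 + 1e-12))

  # causality: nothing before the first toggle
  vs2 <- valve_sequence(0.5, duration = 1)
  tr2 <- valve_to_concentration(vs2, 1)
  expect_true(all(tr2$values[1:499] == 0))
  expect_error(valve_to_concentration(vs2, 1, tau_rise = 0))
})

test_that("protocols round-trip through JSON", {
  p <- make_asynchrony_protocol(48, "B", 0.5, "high")
  json <- protocol_to_json(p)
  p2 <- protocol_from_json(json)
  expect_equal(p2$channels$A$toggle_times, p$channels$A$toggle_times)
  expect_equal(p2$channels$B$toggle_times, p$channels$B$toggle_times)
  expect_equal(p2$onset_asynchrony_ms, p$onset_asynchrony_ms)
  expect_equal(p2$level, p$level)
  expect_equal(p2$t_origin, p$t_origin)
})
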