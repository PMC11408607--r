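test_that("alpha kernel is causal, normalized, and peaks at tau", {
  k <- alpha_kernel(sigma = 0.05, sampling_rate = 1000)
  expect_lt(abs(sum(k) / 1000 - 1), 1e-6)
  expect_true(all(k >= 0))
  expect_equal(k[1], 0)                       # k(0) = 0, nothing before
  expect_equal(which.max(k), 0.05 * 1000 + 1) # argmax at t = tau
  expect_error(alpha_kernel(sigma = 0), "positive")
})

test_that("rate estimation is linear, causal and mass-preserving", {
  # empty train: identically zero
  r0 <- estimate_rate(numeric(), 0.05, t_start = 0, t_end = 1)
  expect_true(all(r0$values == 0))

  # integral of the estimate equals the spike count
  train <- c(0.2, 0.25, 0.4, 0.7)
  rt <- estimate_rate(train, 0.05, t_start = 0, t_end = 2)
  expect_lt(abs(sum(rt$values) / rt$sampling_rate - length(train)) /
              length(train), 0.01)

  # single spike: zero before the spike, peak of e^-1/tau at t0 + tau
  r1 <- estimate_rate(0.5, 0.05, t_start = 0, t_end = 1.5)
  t <- rate_times(r1)
  expect_true(all(r1$values[t <= 0.5] == 0))
  expect_equal(t[which.max(r1$values)], 0.55, tolerance = 2e-3)
  expect_equal(max(r1$values), exp(-1) / 0.05, tolerance = 1e-2)

  # linearity: rate(train1 u train2) = rate(train1) + rate(train2)
  t1 <- c(0.1, 0.3); t2 <- c(0.2, 0.9)
  r12 <- estimate_rate(sort(c(t1, t2)), 0.05, t_start = 0, t_end = 2)
  rsum <- estimate_rate(t1, 0.05, t_start = 0, t_end = 2)$values +
    estimate_rate(t2, 0.05, t_start = 0, t_end = 2)$values
  expect_equal(r12$values, rsum, tolerance = 1e-9)
})

test_that("window metrics use half-open windows in seconds", {
  expect_equal(window_mean_rate(c(0.12, 0.2, 0.25, 0.3, 0.34)), 20)
  expect_equal(window_mean_rate(numeric()), 0)
  # spike exactly at the right edge is excluded
  expect_equal(window_mean_rate(c(0.35)), 0)
  expect_equal(window_mean_rate(c(0.1)), 4)
  expect_error(window_mean_rate(1, window = c(0.5, 0.5)), "positive")
})

test_that("response peak rate and onset latency behave on known traces", {
  ramp <- rate_trace(seq(0, 100, length.out = 500), 1000, t_start = 0)
  expect_equal(response_peak_rate(ramp, c(0, 0.5)), 100)
  expect_equal(response_peak_rate(
    estimate_rate(numeric(), 0.05, 0, 0.5), c(0, 0.5)), 0)
  # single spike: peak equals the kernel maximum
  r1 <- estimate_rate(0.1, 0.05, t_start = 0, t_end = 0.5)
  expect_equal(response_peak_rate(r1, c(0, 0.5)), exp(-1) / 0.05,
               tolerance = 1e-2)
  expect_error(response_peak_rate(ramp, c(2, 3)), "window")

  # flat baseline then a step: crossing within one sample of the step
  vals <- c(rep(10, 500), rep(100, 500)) + rep(c(-0.5, 0.5), 500)
  rt <- rate_trace(vals, 1000, t_start = -0.5)
  lat <- response_onset_latency(rt, baseline_window = c(-0.5, 0),
                                criterion_sd = 3)
  expect_equal(lat, 0, tolerance = 2e-3)
  # never crossing: NA
  expect_true(is.na(response_onset_latency(
    rate_trace(rep(0, 1000) + rep(c(0, 1), 500), 1000, t_start = -0.5),
    baseline_window = c(-0.5, 0))))
  # zero criterion with positive baseline: first sample above the mean
  lat0 <- response_onset_latency(rt, baseline_window = c(-0.5, 0),
                                 criterion_sd = 0)
  expect_equal(lat0, 0, tolerance = 2e-3)
})

test_that("Victor-Purpura distance matches hand-derived cases", {
  expect_equal(as.numeric(victor_purpura_distance(c(0.1, 0.2), c(0.1, 0.2),
                                                  q = 20)), 0)
  expect_equal(as.numeric(victor_purpura_distance(numeric(), c(1, 2, 3),
                                                  q = 20)), 3)
  # {0} vs {0.1} at q = 4: shift (0.4) beats delete+insert (2)
  expect_equal(as.numeric(victor_purpura_distance(0, 0.1, q = 4)), 0.4)
  # at q = 30 the shift (3) loses to delete+insert (2)
  expect_equal(as.numeric(victor_purpura_distance(0, 0.1, q = 30)), 2)
  expect_error(victor_purpura_distance(0, 0.1, q = -1), "non-negative")
})

test_that("dynamic program equals the brute-force matching oracle", {
  # exhaustive: all trains of <= 4 spikes on a fixed grid
  grid <- c(0, 0.12, 0.31, 0.40)
  subsets <- unlist(lapply(0:4, function(k) {
    if (k == 0) list(numeric()) else
      utils::combn(grid, k, simplify = FALSE)
  }), recursive = FALSE)
  for (q in c(0, 4, 25)) {
    for (a in subsets) {
      for (b in subsets) {
        expect_equal(as.numeric(victor_purpura_distance(a, b, q)),
                     bf_victor_purpura(a, b, q), tolerance = 1e-12)
      }
    }
  }
  # random trains of up to 5 spikes
  set.seed(123)
  for (i in 1:200) {
    a <- random_train(); b <- random_train()
    q <- stats::runif(1, 0, 50)
    expect_equal(as.numeric(victor_purpura_distance(a, b, q)),
                 bf_victor_purpura(a, b, q), tolerance = 1e-10)
  }
})

test_that("Victor-Purpura limits in q are exact", {
  set.seed(7)
  for (i in 1:100) {
    a <- random_train(); b <- random_train()
    # q = 0: pure spike-count distance
    expect_equal(as.numeric(victor_purpura_distance(a, b, 0)),
                 abs(length(a) - length(b)))
  }
  # large q: n1 + n2 - 2 * (number of exactly coincident spikes)
  a <- c(0.1, 0.2, 0.5); b <- c(0.2, 0.5, 0.7, 0.9)
  expect_equal(as.numeric(victor_purpura_distance(a, b, 1e9)),
               3 + 4 - 2 * 2)
})

test_that("Victor-Purpura satisfies the metric axioms", {
  set.seed(99)
  q <- 20
  for (i in 1:500) {
    a <- random_train(); b <- random_train(); c_ <- random_train()
    dab <- as.numeric(victor_purpura_distance(a, b, q))
    dba <- as.numeric(victor_purpura_distance(b, a, q))
    dac <- as.numeric(victor_purpura_distance(a, c_, q))
    dbc <- as.numeric(victor_purpura_distance(b, c_, q))
    expect_identical(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dac, dab + dbc + 1e-9)
  }
  expect_equal(as.numeric(victor_purpura_distance(c(0.3, 0.6), c(0.3, 0.6),
                                                  20)), 0)
})
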