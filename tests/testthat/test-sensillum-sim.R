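test_that("transduction gives transient peaks and adapted plateaus", {
  drv <- calibration_drives()
  # drive-level calibration anchors (low concentration)
  expect_gte(max(drv$pulse$values), 70)
  # constant stimulus: plateau read 2 s after onset
  at2s <- drv$constant$values[round(2.5 * drv$constant$sampling_rate)]
  expect_lte(at2s, 25)

  # zero concentration and incognate odorant: constant baseline
  p <- orn_params()
  conc0 <- concentration_trace(rep(0, 500), 1000)
  expect_true(all(transduce(conc0, p)$values == p$baseline_rate))
  conc1 <- concentration_trace(rep(1e-4, 500), 1000)
  expect_true(all(transduce(conc1, p, cognate = FALSE)$values ==
                    p$baseline_rate))
})

test_that("ephaptic coupling is asymmetric, gated and rectified", {
  s <- sensillum_params()
  n <- 100
  # zero gains: identity
  s0 <- sensillum_params(g_AB = 0, g_BA = 0)
  dA <- drive_trace(rep(80, n), 1000)
  dB <- drive_trace(rep(80, n), 1000)
  out0 <- ephaptic_couple(dA, dB, s0)
  expect_equal(out0$A$values, dA$values)
  expect_equal(out0$B$values, dB$values)

  # equal suprabaseline drives: suppression of B exceeds suppression of A
  out <- ephaptic_couple(dA, dB, s)
  supp_B <- dB$values - out$B$values
  supp_A <- dA$values - out$A$values
  expect_true(all(supp_B > supp_A))

  # scaling both drives up increases absolute suppression
  hi <- ephaptic_couple(drive_trace(rep(160, n), 1000),
                        drive_trace(rep(160, n), 1000), s)
  expect_gt(160 - hi$B$values[1], supp_B[1])

  # rectification at zero
  weak <- ephaptic_couple(drive_trace(rep(200, n), 1000),
                          drive_trace(rep(5, n), 1000), s)
  expect_true(all(weak$B$values >= 0))

  expect_error(ephaptic_couple(drive_trace(rep(1, 10), 1000),
                               drive_trace(rep(1, 20), 1000), s),
               "length")
})

test_that("spike generation is a refractory-censored Poisson process", {
  # empty on zero drive
  expect_length(generate_spikes(drive_trace(rep(0, 1000), 1000),
                                0.002, seed = 1)$times, 0)
  # renewal-theory rate for constant drive: r / (1 + r * refractory)
  dr <- drive_trace(rep(100, 100000), 1000)
  st <- generate_spikes(dr, 0.002, seed = 99)
  n_exp <- 100 / (1 + 100 * 0.002) * 100
  expect_lt(abs(length(st$times) - n_exp), 3 * sqrt(n_exp))
  # all inter-spike intervals at or above the refractory period
  expect_true(all(diff(st$times) >= 0.002 - 1e-12))
  # seeded determinism
  expect_identical(generate_spikes(dr, 0.002, seed = 5)$times,
                   generate_spikes(dr, 0.002, seed = 5)$times)
})

test_that("synthesized traces carry rate-dependent amplitudes and truth", {
  s <- sensillum_params()
  # empty trains: pure noise at the configured SD
  tr0 <- synthesize_trace(list(), s, seed = 1, t_start = 0, duration = 10)
  expect_lt(abs(stats::sd(tr0$voltage) - s$noise_sd) / s$noise_sd, 0.05)

  # isolated A spike at baseline local rate: peak near the unit amplitude
  tA <- spike_train(0.5, unit = "A")
  tr1 <- synthesize_trace(list(tA), s, seed = 2, t_start = 0, duration = 1)
  expect_equal(max(tr1$voltage), s$ornA$spike_amplitude, tolerance = 0.15)

  # spikes inside a fast burst are smaller than isolated spikes
  burst <- spike_train(seq(0.2, 0.4, by = 0.005), unit = "A")  # 200/s
  tr2 <- synthesize_trace(list(burst), s, seed = 3, t_start = 0,
                          duration = 1)
  amps <- tr2$truth$amplitude
  expect_lt(amps[length(amps)], amps[1])
  expect_equal(amps[1], s$ornA$spike_amplitude)

  # ground-truth conservation: every spike appears exactly once
  tB <- spike_train(c(0.1, 0.3), unit = "B")
  tr3 <- synthesize_trace(list(tA, tB), s, seed = 4, t_start = 0,
                          duration = 1)
  expect_equal(nrow(tr3$truth), 3)
  expect_setequal(tr3$truth$time, c(0.1, 0.3, 0.5))

  expect_error(synthesize_trace(list(spike_train(5)), s, seed = 1,
                                t_start = 0, duration = 1), "extent")
})

test_that("simulated experiments have the design shape and are seeded", {
  protos <- protocols_asynchrony("low")[c("A", "B", "AB_sync")]
  s <- sensillum_params()
  tt <- simulate_experiment(protos, s, n_flies = 2, n_trials = 3, seed = 10)
  expect_equal(nrow(tt$trains), 2 * 3 * 3 * 2)
  expect_setequal(unique(tt$trains$unit), c("A", "B"))
  tt2 <- simulate_experiment(protos, s, n_flies = 2, n_trials = 3, seed = 10)
  expect_identical(tt$trains$times, tt2$trains$times)

  # adding a trial leaves earlier trials untouched (hierarchical seeding)
  tt3 <- simulate_experiment(protos, s, n_flies = 2, n_trials = 4, seed = 10)
  sub <- tt3$trains[tt3$trains$trial <= 3, ]
  expect_identical(sub$times, tt$trains$times)
})

test_that("incognate-alone stimuli leave the partner at baseline activity", {
  # a B pulse alone must not excite unit A beyond its spontaneous rate
  protos <- protocols_asynchrony("low")["B"]
  tt <- simulate_experiment(protos, sensillum_params(), 2, 5, seed = 3)
  trA <- tt$trains[tt$trains$unit == "A", ]
  rates <- vapply(trA$times, function(x) window_mean_rate(x, c(0, 0.5)),
                  numeric(1))
  expect_lt(mean(rates), 10)
})

test_that("suppression grows with concentration and shrinks with asynchrony", {
  # background-pulse suppression: high concentration beats low
  supp <- vapply(c("low", "high"), function(lev) {
    r <- run_experiment(run_config("fig2", seed = 21, level = lev,
                                   n_flies = 4))
    pt <- r$paired_tests
    1 - pt$mean_mixed[1] / pt$mean_alone[1]
  }, numeric(1))
  expect_gt(supp[["high"]], supp[["low"]])
  expect_gt(supp[["low"]], 0)

  # monotone decline of B's peak-rate suppression across the grid
  r3 <- run_experiment(run_config("fig3", seed = 22, n_flies = 4,
                                  n_trials = 5))
  b <- r3$battery[r3$battery$unit == "B", ]
  b$adt <- abs(b$onset_asynchrony_ms)
  mean_supp <- tapply(1 - b$mean_normalized, b$adt, mean)
  expect_lt(cor(as.numeric(names(mean_supp)), mean_supp,
                method = "spearman"), 0)
  # responses recover with asynchrony: positive pooled regression slope
  expect_gt(r3$regression$average$slope, 0)
})
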