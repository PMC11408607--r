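test_that("paired t test handles standard and degenerate input", {
  r0 <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # constant nonzero differences: zero variance, flagged
  rd <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(rd$degenerate)

  # five chosen pairs against the closed-form t statistic
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9)
  y <- c(4.2, 4.9, 5.1, 5.0, 5.2)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  r <- paired_t_test(x, y)
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$p, p_hand, tolerance = 1e-10)

  expect_error(paired_t_test(1, 1), "length")
})

test_that("cognate normalization divides by per-fly cognate means", {
  tbl <- data.frame(
    fly_id = rep(1:2, each = 4),
    stimulus_id = rep(c("A", "A", "AB_sync", "AB_sync"), 2),
    onset_asynchrony_ms = rep(c(NA, NA, 0, 0), 2),
    mixture_mode = "none", level = "low",
    trial = rep(1:2, 4), unit = "A", metric = "peak_rate",
    value = c(10, 30, 10, 10, 40, 40, 20, 20)
  )
  norm <- normalize_to_cognate(tbl)
  # cognate-alone means are 1 per fly
  for (f in 1:2) {
    expect_equal(mean(norm$value[norm$fly_id == f &
                                   norm$stimulus_id == "A"]), 1)
  }
  # a value equal to half the cognate mean becomes 0.5
  expect_equal(norm$value[norm$fly_id == 1 &
                            norm$stimulus_id == "AB_sync"], c(0.5, 0.5))
  expect_equal(norm$value[norm$fly_id == 2 &
                            norm$stimulus_id == "AB_sync"], c(0.5, 0.5))

  # relabeling flies commutes with normalization
  perm <- tbl
  perm$fly_id <- 3 - perm$fly_id
  norm_perm <- normalize_to_cognate(perm)
  expect_equal(norm_perm$value, norm$value)

  bad <- tbl
  bad$value[bad$stimulus_id == "A" & bad$fly_id == 1] <- 0
  expect_error(normalize_to_cognate(bad), "zero")
})

test_that("FDR adjustment is Benjamini-Hochberg step-up", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- stats::runif(50)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("asynchrony battery tests each mixture against cognate alone", {
  # deterministic synthetic normalized table: unit B suppressed at 0 ms only
  flies <- 1:6
  stims <- c("B", "AB_sync", "A96B")
  set.seed(11)
  rows <- expand.grid(fly_id = flies, stimulus_id = stims, trial = 1:4)
  rows$unit <- "B"
  rows$level <- "low"
  rows$mixture_mode <- "none"
  rows$onset_asynchrony_ms <- c(B = NA, AB_sync = 0, A96B = 96)[
    as.character(rows$stimulus_id)]
  rows$metric <- "peak_rate"
  base <- 50 + 5 * rows$fly_id
  eff <- ifelse(rows$stimulus_id == "AB_sync", 0.5, 1)
  rows$value <- base * eff * exp(stats::rnorm(nrow(rows), 0, 0.03))
  norm <- normalize_to_cognate(rows, cognate_map = c(B = "B"))
  bat <- asynchrony_test_battery(norm, cognate_map = c(B = "B"))
  expect_equal(nrow(bat), 2)
  expect_lt(bat$p_adjusted[bat$stimulus_id == "AB_sync"], 0.05)
  expect_gt(bat$p_adjusted[bat$stimulus_id == "A96B"], 0.05)
  expect_true(all(bat$p_adjusted >= bat$p))

  # a single fly is not enough
  one_fly <- norm[norm$fly_id == 1, ]
  expect_error(asynchrony_test_battery(one_fly, cognate_map = c(B = "B")),
               "2 flies")
})

test_that("synchrony window width sums the significant flanks", {
  mk <- function(dt, q) data.frame(unit = "B", stimulus_id = "x",
                                   onset_asynchrony_ms = dt,
                                   mean_normalized = 0.7, statistic = -5,
                                   p = q, n = 8, p_adjusted = q,
                                   method = "BH")
  bat <- do.call(rbind, c(
    lapply(c(0, 3, 6, 12, 24, 48), function(d) mk(d, 0.01)),
    lapply(c(3, 6, 12, 24), function(d) mk(-d, 0.01)),
    list(mk(96, 0.5), mk(-48, 0.5), mk(-96, 0.5))
  ))
  expect_equal(as.numeric(synchrony_window_width(bat, "B")), 72)

  bat_ns <- bat
  bat_ns$p_adjusted <- 0.9
  w0 <- synchrony_window_width(bat_ns, "B")
  expect_equal(as.numeric(w0), 0)
  expect_true(attr(w0, "none_significant"))
})

test_that("pooled synchrony regression recovers exact linear structure", {
  # perfectly linear per-fly data: value = 0.6 + 0.002 * |dt|
  dts <- c(0, 3, 6, 12, 24, 48, 96)
  tbl <- expand.grid(fly_id = 1:4, onset_asynchrony_ms = c(dts, -dts))
  tbl$unit <- "B"
  tbl$value <- 0.6 + 0.002 * abs(tbl$onset_asynchrony_ms)
  # summary.lm warns about the (intentionally) perfect fit
  reg <- suppressWarnings(pooled_synchrony_regression(tbl, unit = "B"))
  expect_equal(reg$average$slope, 0.002, tolerance = 1e-12)
  expect_equal(reg$average$r_squared, 1)
  expect_equal(reg$per_fly$slope, rep(0.002, 4), tolerance = 1e-12)

  few <- tbl[abs(tbl$onset_asynchrony_ms) %in% c(0, 3), ]
  expect_error(pooled_synchrony_regression(few, "B"), "3 distinct")
})

test_that("distance groups count within-fly trial pairs correctly", {
  # two flies x 5 trials of two deterministic stimuli
  mk_train <- function(fly, stim, trial, times) {
    data.frame(fly_id = fly, stimulus_id = stim,
               onset_asynchrony_ms = NA, mixture_mode = stim,
               level = "high", trial = trial, unit = "B")
  }
  rows <- do.call(rbind, lapply(1:2, function(f) {
    do.call(rbind, lapply(1:5, function(tr) {
      rbind(mk_train(f, "B", tr), mk_train(f, "AB_i", tr))
    }))
  }))
  rows$times <- rep(list(c(0.1, 0.2, 0.3)), nrow(rows))
  tt <- trial_table(rows, protocols = NULL, params = NULL)
  d <- dvp_comparison_groups(tt, q = 20,
                             pairs = list(c("B", "B"), c("AB_i", "B")),
                             unit = "B")
  # identical deterministic trains: all distances zero
  expect_true(all(d$d_vp == 0))
  # C(5,2) = 10 same-stimulus pairs and 5 x 5 = 25 cross pairs per fly
  expect_equal(sum(d$pair == "(B, B)"), 2 * 10)
  expect_equal(sum(d$pair == "(AB_i, B)"), 2 * 25)
  expect_error(dvp_comparison_groups(tt, pairs = list(c("AB_B", "B")),
                                     unit = "B"), "missing")
})

test_that("U tests with Bonferroni correction behave at the extremes", {
  g <- list(x = c(1:10), y = c(11:20), z = c(1:10) + 0.5)
  res <- utest_bonferroni(g, list(c("x", "y"), c("x", "z")))
  # complete separation: U = 0 (or 100), minimal normal-approx p, doubled
  r_xy <- res[res$comparison == "x vs y", ]
  expect_true(r_xy$statistic %in% c(0, 100))
  expect_lt(r_xy$p_adjusted, 0.01)
  expect_equal(r_xy$p_adjusted, min(1, r_xy$p * 2))

  # identical groups: p near 1
  same <- utest_bonferroni(list(a = rep(1:5, 4), b = rep(1:5, 4)),
                           list(c("a", "b")))
  expect_gt(same$p, 0.9)
  # m = 1 leaves p unchanged
  expect_equal(same$p_adjusted, same$p)

  expect_error(utest_bonferroni(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("battery decisions are invariant to per-fly rescaling", {
  protos <- protocols_asynchrony("low")[c("A", "B", "AB_sync", "A48B")]
  tt <- simulate_experiment(protos, sensillum_params(), 4, 5, seed = 31)
  resp <- compute_response_table(tt, "peak_rate")
  bat1 <- asynchrony_test_battery(normalize_to_cognate(resp))
  scaled <- resp
  scale_map <- c(2, 0.5, 3, 1.7)
  scaled$value <- scaled$value * scale_map[scaled$fly_id]
  bat2 <- asynchrony_test_battery(normalize_to_cognate(scaled))
  expect_equal(bat1$p, bat2$p, tolerance = 1e-9)
})
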