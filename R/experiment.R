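#' Trial table of a simulated experiment
#'
#' Holds one row per (fly, stimulus, trial, unit) with the ground-truth spike
#' train as a list column, plus the protocols and parameters that produced
#' it. Synthesized voltage traces, when requested, live in `traces`, keyed by
#' `"fly<f>:<stimulus>:<trial>"`.
#'
#' @param trains Data frame with columns `fly_id`, `stimulus_id`,
#'   `onset_asynchrony_ms`, `mixture_mode`, `level`, `trial`, `unit`, and the
#'   list column `times`.
#' @param protocols Named list of [stimulus_protocol()]s.
#' @param params The [sensillum_params()] used.
#' @param traces Optional named list of [recording_trace()]s.
#' @return An object of class `trial_table`.
#' @export
trial_table <- function(trains, protocols, params, traces = NULL) {
  key <- paste(trains$fly_id, trains$stimulus_id, trains$trial, trains$unit)
  if (anyDuplicated(key)) stop("(fly, stimulus, trial, unit) must be unique")
  structure(list(trains = trains, protocols = protocols, params = params,
                 traces = traces),
            class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  tr <- x$trains
  cat(sprintf(
    "<trial_table> %d flies x %d stimuli x %d trials (%d trains, %d spikes)%s\n",
    length(unique(tr$fly_id)), length(unique(tr$stimulus_id)),
    max(tr$trial), nrow(tr), sum(lengths(tr$times)),
    if (!is.null(x$traces)) sprintf(", %d voltage traces", length(x$traces))
    else ""))
  invisible(x)
}

# lognormal jitter with mean 1 and coefficient of variation cv
jitter_lognorm <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# slowly varying response gain: stationary lognormal OU process with unit
# mean, stationary CV `cv` and correlation time `tau`, sampled at `rate`
gain_process <- function(n, cv, tau, rate) {
  if (cv <= 0 || n == 0L) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rho <- exp(-1 / (rate * tau))
  z <- numeric(n)
  z[1L] <- stats::rnorm(1L, 0, sdlog)
  if (n > 1L) {
    innov <- stats::rnorm(n - 1L, 0, sdlog * sqrt(1 - rho^2))
    z[-1L] <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                       init = z[1L]))
  }
  exp(z - sdlog^2 / 2)
}

# per-fly parameter jitter: multiplicative lognormal on response gain,
# spike amplitude and coupling strengths
jitter_fly_params <- function(s, fly_seed) {
  local_seed(fly_seed, {
    j <- jitter_lognorm(6L, s$fly_jitter_cv)
    s$ornA$max_rate <- s$ornA$max_rate * j[1L]
    s$ornB$max_rate <- s$ornB$max_rate * j[2L]
    s$ornA$spike_amplitude <- s$ornA$spike_amplitude * j[3L]
    s$ornB$spike_amplitude <- s$ornB$spike_amplitude * j[4L]
    s$g_AB <- s$g_AB * j[5L]
    s$g_BA <- s$g_BA * j[6L]
    s
  })
}

#' Simulate a whole multi-fly experiment
#'
#' For each simulated fly, ORN and coupling parameters are jittered
#' (multiplicative lognormal, CV `fly_jitter_cv`); for each protocol the
#' valve sequences are converted to concentration traces, transduced into
#' drives (channel A is the cognate odorant of neuron A and incognate for B,
#' and vice versa), and coupled; each trial then draws spike trains from the
#' coupled drives, optionally with a synthesized voltage trace. Seeding is
#' hierarchical (experiment, then fly, then trial), so adding flies or trials
#' does not perturb existing ones.
#'
#' @param protocols Named list of [stimulus_protocol()]s (names become
#'   `stimulus_id`).
#' @param s A [sensillum_params()].
#' @param n_flies,n_trials Design size (>= 1).
#' @param seed Master integer seed.
#' @param synthesize Also synthesize extracellular voltage traces?
#' @return A [trial_table()].
#' @export
simulate_experiment <- function(protocols, s = sensillum_params(),
                                n_flies = 8, n_trials = 10, seed = 1,
                                synthesize = FALSE) {
  stopifnot(inherits(s, "sensillum_params"), n_flies >= 1, n_trials >= 1,
            length(protocols) >= 1, !is.null(names(protocols)))
  rows <- vector("list", n_flies * length(protocols) * n_trials * 2L)
  traces <- if (synthesize) list() else NULL
  ri <- 0L
  for (f in seq_len(n_flies)) {
    sf <- jitter_fly_params(s, derive_seed(seed, f, 0L))
    for (pn in names(protocols)) {
      pr <- protocols[[pn]]
      peak <- s$conc_peaks[[pr$level]]
      concA <- valve_to_concentration(pr$channels$A, peak, s$tau_rise,
                                      s$tau_fall, s$drive_rate,
                                      t0 = pr$t_origin)
      concB <- valve_to_concentration(pr$channels$B, peak, s$tau_rise,
                                      s$tau_fall, s$drive_rate,
                                      t0 = pr$t_origin)
      dA <- transduce(concA, sf$ornA, cognate = TRUE)
      dB <- transduce(concB, sf$ornB, cognate = TRUE)
      coupled <- ephaptic_couple(dA, dB, sf)
      p_idx <- match(pn, names(protocols))
      base_vals <- list(A = coupled$A$values, B = coupled$B$values)
      for (tr in seq_len(n_trials)) {
        gain <- local_seed(derive_seed(seed, f, p_idx, tr, 4L),
                           gain_process(length(base_vals$A),
                                        s$trial_gain_cv, s$trial_gain_tau,
                                        s$drive_rate))
        coupled$A$values <- base_vals$A * gain
        coupled$B$values <- base_vals$B * gain
        tA <- generate_spikes(coupled$A, sf$ornA$refractory,
                              derive_seed(seed, f, p_idx, tr, 1L),
                              unit = "A", fly_id = f, stimulus_id = pn,
                              trial_index = tr)
        tB <- generate_spikes(coupled$B, sf$ornB$refractory,
                              derive_seed(seed, f, p_idx, tr, 2L),
                              unit = "B", fly_id = f, stimulus_id = pn,
                              trial_index = tr)
        for (train in list(tA, tB)) {
          ri <- ri + 1L
          rows[[ri]] <- list(fly_id = f, stimulus_id = pn,
                             onset_asynchrony_ms = pr$onset_asynchrony_ms,
                             mixture_mode = pr$mixture_mode,
                             level = pr$level, trial = tr,
                             unit = train$unit, times = list(train$times))
        }
        if (synthesize) {
          tr_key <- sprintf("fly%d:%s:%d", f, pn, tr)
          traces[[tr_key]] <- synthesize_trace(
            list(tA, tB), sf, seed = derive_seed(seed, f, p_idx, tr, 3L),
            t_start = -pr$t_origin,
            duration = pr$duration)
        }
      }
    }
  }
  rows <- rows[seq_len(ri)]
  trains <- data.frame(
    fly_id = vapply(rows, `[[`, numeric(1), "fly_id"),
    stimulus_id = vapply(rows, `[[`, character(1), "stimulus_id"),
    onset_asynchrony_ms = vapply(rows, `[[`, numeric(1),
                                 "onset_asynchrony_ms"),
    mixture_mode = vapply(rows, `[[`, character(1), "mixture_mode"),
    level = vapply(rows, `[[`, character(1), "level"),
    trial = vapply(rows, `[[`, numeric(1), "trial"),
    unit = vapply(rows, `[[`, character(1), "unit")
  )
  trains$times <- lapply(rows, function(r) r$times[[1L]])
  trial_table(trains, protocols, s, traces)
}

#' Stimulus sets of the three experimental designs
#'
#' `protocols_asynchrony()` builds the 15-stimulus onset-asynchrony set:
#' single pulses of A and of B, the synchronous mixture, and the asynchrony
#' grid (3, 6, 12, 24, 48, 96 ms) with either odorant leading.
#' `protocols_background_pulse()` builds the background-plus-pulse set: each
#' odorant pulsed alone and into a sustained background of the other.
#' `protocols_fluctuating()` builds the five fluctuating-mixture stimuli
#' from two Poisson-switched base sequences.
#'
#' @param level Concentration level for all protocols.
#' @param dt_grid Nonzero asynchronies in milliseconds.
#' @param pulse_duration Pulse length in seconds.
#' @param duration Fluctuating-segment length in seconds.
#' @param mean_interval Mean Poisson switching interval in seconds.
#' @param seedA,seedB Seeds of the two fluctuating base sequences.
#' @return Named list of [stimulus_protocol()]s.
#' @export
protocols_asynchrony <- function(level = "low",
                                 dt_grid = c(3, 6, 12, 24, 48, 96),
                                 pulse_duration = 0.5) {
  out <- list(
    A = make_pulse_protocol("A", pulse_duration, level),
    B = make_pulse_protocol("B", pulse_duration, level),
    AB_sync = make_asynchrony_protocol(0, "A", pulse_duration, level)
  )
  for (dt in dt_grid) {
    for (lead in c("A", "B")) {
      p <- make_asynchrony_protocol(dt, lead, pulse_duration, level)
      out[[p$label]] <- p
    }
  }
  out
}

#' @rdname protocols_asynchrony
#' @export
protocols_background_pulse <- function(level = "high",
                                       pulse_duration = 0.5) {
  list(
    A = make_pulse_protocol("A", pulse_duration, level),
    B = make_pulse_protocol("B", pulse_duration, level),
    `A on B` = make_background_pulse_protocol("B", "A",
                                              pulse_duration = pulse_duration,
                                              level = level),
    `B on A` = make_background_pulse_protocol("A", "B",
                                              pulse_duration = pulse_duration,
                                              level = level)
  )
}

#' @rdname protocols_asynchrony
#' @export
protocols_fluctuating <- function(level = "high", duration = 10,
                                  mean_interval = 0.05,
                                  seedA = 101, seedB = 202) {
  make_fluctuating_mixture_set(duration, mean_interval, seedA, seedB,
                               level = level)
}
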