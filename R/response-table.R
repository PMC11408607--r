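#' Per-trial response metrics from a trial table
#'
#' Computes one response metric per (fly, stimulus, trial, unit):
#' `"peak_rate"` — single-trial response peak rate from the alpha-kernel
#' rate estimate; `"window_mean_rate"` — spike count rate in a fixed window;
#' `"onset_latency"` — first sustained threshold crossing after t = 0.
#' All windows are half-open `[a, b)` in analysis time (t = 0 at the leading
#' valve opening).
#'
#' Two peak readouts are available. `"mean_argmax"` (default) locates the
#' response peak on each fly's trial-averaged rate for the stimulus and
#' reads every trial's rate at that time; this estimates the single-trial
#' rate at the response peak without the upward bias and window sensitivity
#' of a per-trial maximum (the maximum of a noisy rate estimate over a
#' window is systematically pulled toward whichever part of the window has
#' elevated rate, not just the peak). `"trial_max"` takes each trial's
#' maximum within the window.
#'
#' @param tt A [trial_table()].
#' @param metric One of `"peak_rate"`, `"window_mean_rate"`,
#'   `"onset_latency"`.
#' @param window Quantification/search window, seconds.
#' @param sigma Alpha-kernel time constant for rate-based metrics, seconds.
#' @param rate_sampling Rate-grid sampling rate, Hz.
#' @param baseline_window Baseline window for `"onset_latency"`.
#' @param peak_readout `"mean_argmax"` or `"trial_max"` (see Details).
#' @return A response table: data frame with the trial keys plus `metric`
#'   and `value`.
#' @export
compute_response_table <- function(tt, metric = c("peak_rate",
                                                  "window_mean_rate",
                                                  "onset_latency"),
                                   window = NULL, sigma = 0.050,
                                   rate_sampling = 1000,
                                   baseline_window = c(-0.4, 0),
                                   peak_readout = c("mean_argmax",
                                                    "trial_max")) {
  stopifnot(inherits(tt, "trial_table"))
  metric <- match.arg(metric)
  peak_readout <- match.arg(peak_readout)
  window <- window %||% switch(metric,
                               peak_rate = c(0, 0.5),
                               window_mean_rate = c(0.1, 0.35),
                               onset_latency = c(0, 0.5))
  tr <- tt$trains
  value <- numeric(nrow(tr))
  if (metric == "peak_rate") {
    group <- interaction(tr$fly_id, tr$stimulus_id, tr$unit, drop = TRUE)
    for (g in levels(group)) {
      idx <- which(group == g)
      rates <- lapply(idx, function(i) {
        estimate_rate(tr$times[[i]], sigma, t_start = window[1],
                      t_end = window[2], sampling_rate = rate_sampling)$values
      })
      if (peak_readout == "mean_argmax" && length(idx) > 1L) {
        t_star <- which.max(Reduce(`+`, rates))
        value[idx] <- vapply(rates, `[`, numeric(1), t_star)
      } else {
        value[idx] <- vapply(rates, max, numeric(1))
      }
    }
  } else {
    for (i in seq_len(nrow(tr))) {
      times <- tr$times[[i]]
      value[i] <- switch(
        metric,
        window_mean_rate = window_mean_rate(times, window),
        onset_latency = {
          rt <- estimate_rate(times, sigma, t_start = baseline_window[1],
                              t_end = window[2],
                              sampling_rate = rate_sampling)
          response_onset_latency(rt, baseline_window)
        }
      )
    }
  }
  out <- tr[c("fly_id", "stimulus_id", "onset_asynchrony_ms", "mixture_mode",
              "level", "trial", "unit")]
  out$metric <- metric
  out$value <- value
  out
}

#' Replace ground-truth trains with sorted trains
#'
#' Runs detection on every synthesized voltage trace of a trial table and
#' sorts all of a fly's events jointly — the trials of one fly come from one
#' recording session, so they share one amplitude model and give both units
#' enough events even in trials where one neuron is nearly silent. Trials
#' are laid end to end with a spacer long enough that the causal local-rate
#' estimate resets between them. Returns a new trial table whose spike
#' trains are the sorted ones.
#'
#' @param tt A [trial_table()] with voltage traces (simulated with
#'   `synthesize = TRUE`).
#' @param threshold_mads Detection threshold.
#' @param ... Passed to [sort_two_units()].
#' @return A [trial_table()] with sorted trains (same keys).
#' @export
sort_trial_table <- function(tt, threshold_mads = 5, ...) {
  stopifnot(inherits(tt, "trial_table"))
  if (is.null(tt$traces)) stop("trial table has no voltage traces to sort")
  tr <- tt$trains
  new_times <- tr$times
  keys <- sprintf("fly%d:%s:%d", tr$fly_id, tr$stimulus_id, tr$trial)
  for (fly in unique(tr$fly_id)) {
    fly_keys <- unique(keys[tr$fly_id == fly])
    ev_list <- vector("list", length(fly_keys))
    offsets <- numeric(length(fly_keys))
    offset <- 0
    for (k in seq_along(fly_keys)) {
      trace <- tt$traces[[fly_keys[k]]]
      if (is.null(trace)) stop("missing trace for trial ", fly_keys[k])
      events <- bandpass_and_detect(trace, threshold_mads = threshold_mads)
      offsets[k] <- offset - trace$t_start
      events$session_time <- events$time + offsets[k]
      ev_list[[k]] <- events
      # 2-s spacer so local-rate estimates decay between trials
      offset <- offset + length(trace$voltage) / trace$sampling_rate + 2
    }
    all_ev <- do.call(rbind, ev_list)
    all_ev <- all_ev[order(all_ev$session_time), ]
    if (nrow(all_ev) < 2L) next
    srt <- sort_two_units(data.frame(time = all_ev$session_time,
                                     peak_amplitude = all_ev$peak_amplitude,
                                     trough_amplitude =
                                       all_ev$trough_amplitude), ...)
    unit_lab <- srt$events$unit
    for (k in seq_along(fly_keys)) {
      trace <- tt$traces[[fly_keys[k]]]
      t_lo <- offsets[k] + trace$t_start
      t_hi <- t_lo + length(trace$voltage) / trace$sampling_rate
      in_trial <- srt$events$time >= t_lo & srt$events$time < t_hi
      idx <- which(keys == fly_keys[k])
      for (i in idx) {
        sel <- in_trial & unit_lab == tr$unit[i]
        new_times[[i]] <- srt$events$time[sel] - offsets[k]
      }
    }
  }
  tr$times <- new_times
  trial_table(tr, tt$protocols, tt$params, tt$traces)
}
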