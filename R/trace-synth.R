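#' Synthetic extracellular recording trace
#'
#' @param voltage Numeric vector, mV per sample.
#' @param sampling_rate Hz.
#' @param t_start Analysis time of the first sample, seconds.
#' @param truth Optional data frame of ground-truth events with columns
#'   `time`, `unit` (and `amplitude` when synthesized).
#' @return An object of class `recording_trace`.
#' @export
recording_trace <- function(voltage, sampling_rate, t_start = 0,
                            truth = NULL) {
  stopifnot(sampling_rate > 0, all(is.finite(voltage)))
  structure(list(voltage = as.numeric(voltage),
                 sampling_rate = sampling_rate,
                 t_start = t_start, truth = truth),
            class = "recording_trace")
}

#' @export
print.recording_trace <- function(x, ...) {
  cat(sprintf("<recording_trace> %.3f s @ %g Hz, SD %.3f mV%s\n",
              length(x$voltage) / x$sampling_rate, x$sampling_rate,
              stats::sd(x$voltage),
              if (!is.null(x$truth)) sprintf(", %d ground-truth events",
                                             nrow(x$truth)) else ""))
  invisible(x)
}

#' @export
plot.recording_trace <- function(x, ...) {
  t <- x$t_start + (seq_along(x$voltage) - 1) / x$sampling_rate
  graphics::plot(t, x$voltage, type = "l", xlab = "time (s)",
                 ylab = "voltage (mV)", ...)
  if (!is.null(x$truth)) {
    graphics::points(x$truth$time,
                     rep(max(x$voltage) * 1.05, nrow(x$truth)),
                     pch = "|", col = ifelse(x$truth$unit == "A", 4, 2))
  }
  invisible(x)
}

# biphasic spike template: one sine cycle over the spike width, unit peak
spike_template <- function(width_s, sampling_rate) {
  n <- max(4L, round(width_s * sampling_rate))
  ph <- (seq_len(n) - 0.5) / n
  sin(2 * pi * ph)
}

# causal local rate at each spike from preceding same-unit spikes:
# exponential window with time constant tau (one-sided)
causal_local_rate <- function(times, tau = 0.1) {
  n <- length(times)
  if (n == 0L) return(numeric())
  r <- numeric(n)
  s <- 0
  for (i in seq_len(n)) {
    if (i > 1L) s <- (s + 1 / tau) * exp(-(times[i] - times[i - 1L]) / tau)
    r[i] <- s
  }
  r
}

#' Synthesize an extracellular voltage trace from spike trains
#'
#' Every spike adds a biphasic waveform at its time. The per-spike peak
#' amplitude declines exponentially with the unit's local firing rate
#' (`amplitude * exp(-amp_rate_decay * rate)`), where the local rate is
#' estimated causally from the preceding spikes of the same unit — the
#' characteristic spike-shape change of sensillum recordings during bursts.
#' White Gaussian noise of SD `noise_sd` is added. Ground truth (time, unit,
#' amplitude) is retained on the returned trace.
#'
#' @param trains List of [spike_train()]s with units `"A"`/`"B"` (times in
#'   analysis seconds).
#' @param s A [sensillum_params()].
#' @param seed Integer seed for the noise.
#' @param t_start,duration Trace extent in analysis time, seconds.
#' @param rate_tau Time constant of the causal local-rate estimate, seconds.
#' @return A [recording_trace()] with `truth` attached.
#' @export
synthesize_trace <- function(trains, s, seed, t_start, duration,
                             rate_tau = 0.1) {
  stopifnot(inherits(s, "sensillum_params"), duration > 0)
  sr <- s$sampling_rate
  widest <- max(s$ornA$spike_width, s$ornB$spike_width) / 1000
  if (sr < 4 / widest) {
    stop("sampling_rate too low to resolve the spike width")
  }
  n <- round(duration * sr)
  v <- numeric(n)
  truth <- list()
  for (tr in trains) {
    p <- if (identical(tr$unit, "A")) s$ornA else s$ornB
    times <- tr$times
    if (any(times < t_start | times > t_start + duration)) {
      stop("spike times outside the trace extent")
    }
    if (!length(times)) next
    rate <- causal_local_rate(times, tau = rate_tau)
    amps <- p$spike_amplitude * exp(-p$amp_rate_decay * rate)
    tmpl <- spike_template(p$spike_width / 1000, sr)
    m <- length(tmpl)
    # align the template's positive peak (quarter period) with the spike time
    start_idx <- round((times - t_start) * sr) + 1L - round(m / 4)
    for (k in seq_along(times)) {
      i0 <- start_idx[k]
      i1 <- min(i0 + m - 1L, n)
      if (i0 <= n && i1 >= 1L) {
        j0 <- max(i0, 1L)
        v[j0:i1] <- v[j0:i1] + amps[k] * tmpl[(j0 - i0 + 1L):(i1 - i0 + 1L)]
      }
    }
    truth[[length(truth) + 1L]] <-
      data.frame(time = times, unit = tr$unit, amplitude = amps)
  }
  noise <- local_seed(seed, stats::rnorm(n, 0, s$noise_sd))
  truth <- if (length(truth)) {
    tt <- do.call(rbind, truth)
    tt[order(tt$time), , drop = FALSE]
  } else {
    data.frame(time = numeric(), unit = character(), amplitude = numeric())
  }
  recording_trace(v + noise, sr, t_start = t_start, truth = truth)
}
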