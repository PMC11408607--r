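#' Continuous odorant concentration trace
#'
#' Emulates the signal a fast photoionization detector would report at the
#' stimulus outlet: a dimensionless concentration fraction sampled at a fixed
#' rate. `t0` records the analysis time origin (leading valve opening) in
#' trace time, so sample `i` sits at `(i - 1) / sampling_rate - t0` on the
#' analysis axis.
#'
#' @param values Numeric vector of non-negative concentration fractions.
#' @param sampling_rate Samples per second.
#' @param t0 Analysis origin in seconds from the first sample.
#' @return An object of class `concentration_trace`.
#' @export
concentration_trace <- function(values, sampling_rate, t0 = 0) {
  stopifnot(sampling_rate > 0, all(values >= 0))
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
                 t0 = t0),
            class = "concentration_trace")
}

#' @export
print.concentration_trace <- function(x, ...) {
  cat(sprintf(
    "<concentration_trace> %d samples @ %g Hz (%.3f s), peak %.3g\n",
    length(x$values), x$sampling_rate,
    length(x$values) / x$sampling_rate, max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.concentration_trace <- function(x, ...) {
  data.frame(time_s = (seq_along(x$values) - 1) / x$sampling_rate - x$t0,
             concentration = x$values)
}

#' Convert a valve sequence to a concentration trace
#'
#' First-order low-pass of the binary valve state, scaled to the peak
#' concentration: the concentration relaxes exponentially toward `peak_conc`
#' with time constant `tau_rise` while the valve is open and decays toward
#' zero with `tau_fall` while closed. The asymmetric time constants emulate
#' the fast-but-not-square onset and the slightly slower washout seen in PID
#' measurements; the exact dynamics of the physical system are not critical
#' and both taus are configurable. Evaluated segment-wise in closed form, so
#' the result is exact at the sample points.
#'
#' @param seq A [valve_sequence()].
#' @param peak_conc Steady-state open-valve concentration fraction.
#' @param tau_rise,tau_fall Rise and fall time constants, seconds (> 0).
#' @param sampling_rate Output sampling rate, Hz.
#' @param t0 Analysis origin, seconds from trace start.
#' @return A [concentration_trace()]; causal (zero before the first opening)
#'   and bounded by `peak_conc`.
#' @export
valve_to_concentration <- function(seq, peak_conc, tau_rise = 0.020,
                                   tau_fall = 0.040, sampling_rate = 1000,
                                   t0 = 0) {
  stopifnot(inherits(seq, "valve_sequence"),
            tau_rise > 0, tau_fall > 0, sampling_rate > 0, peak_conc >= 0)
  n <- round(seq$duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  values <- numeric(n)
  edges <- c(0, seq$toggle_times, seq$duration)
  state <- seq$initial_state == "open"
  v0 <- 0
  for (k in seq_len(length(edges) - 1L)) {
    lo <- edges[k]; hi <- edges[k + 1L]
    idx <- which(t >= lo & t < hi)
    target <- if (state) peak_conc else 0
    tau <- if (state) tau_rise else tau_fall
    if (length(idx)) {
      values[idx] <- target + (v0 - target) * exp(-(t[idx] - lo) / tau)
    }
    v0 <- target + (v0 - target) * exp(-(hi - lo) / tau)
    state <- !state
  }
  concentration_trace(pmax(values, 0), sampling_rate, t0 = t0)
}
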