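#' Timed valve state sequence for one odorant channel
#'
#' A valve sequence encodes the command signal sent to one solenoid valve of
#' the odor stimulator as a list of toggle times plus the initial state. The
#' valve state at any time point is recovered by counting toggles, so the
#' representation is exact at any sampling rate; dense binary traces are
#' derived views (see [valve_state()]).
#'
#' @param toggle_times Numeric vector of toggle times in seconds, strictly
#'   increasing, all in `[0, duration)`.
#' @param duration Total sequence duration in seconds.
#' @param initial_state `"closed"` (default) or `"open"`.
#' @param channel Odorant channel label, `"A"` (methyl hexanoate, the ab3A
#'   ligand) or `"B"` (2-heptanone, the ab3B ligand).
#' @return An object of class `valve_sequence`.
#' @seealso [poisson_valve_sequence()], [valve_to_concentration()]
#' @export
valve_sequence <- function(toggle_times = numeric(), duration,
                           initial_state = c("closed", "open"),
                           channel = "A") {
  initial_state <- match.arg(initial_state)
  toggle_times <- as.numeric(toggle_times)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration >= 0)
  if (anyNA(toggle_times)) stop("toggle_times must not contain NA")
  if (is.unsorted(toggle_times, strictly = TRUE)) {
    stop("toggle_times must be strictly increasing")
  }
  if (length(toggle_times) &&
      (toggle_times[1L] < 0 || toggle_times[length(toggle_times)] >= duration)) {
    stop("all toggle_times must lie in [0, duration)")
  }
  structure(
    list(toggle_times = toggle_times, initial_state = initial_state,
         duration = duration, channel = channel),
    class = "valve_sequence"
  )
}

#' @export
print.valve_sequence <- function(x, ...) {
  cat(sprintf("<valve_sequence> channel %s, %.3f s, %d toggles, starts %s\n",
              x$channel, x$duration, length(x$toggle_times), x$initial_state))
  invisible(x)
}

#' Valve state at given times
#'
#' @param seq A [valve_sequence()].
#' @param t Numeric vector of times in seconds.
#' @return Logical vector, `TRUE` where the valve is open. Times outside
#'   `[0, duration)` are closed unless the initial state is open and `t < 0`
#'   counts zero toggles; by convention the sequence does not exist outside
#'   its duration, so state there is the initial state (before 0) or the
#'   final state (at or after duration).
#' @export
valve_state <- function(seq, t) {
  stopifnot(inherits(seq, "valve_sequence"))
  n_toggles <- findInterval(t, seq$toggle_times)
  open0 <- seq$initial_state == "open"
  xor(open0, n_toggles %% 2L == 1L)
}

#' Total valve-open time
#'
#' @param seq A [valve_sequence()].
#' @return Open time in seconds, summed over the sequence duration.
#' @export
valve_open_time <- function(seq) {
  edges <- c(0, seq$toggle_times, seq$duration)
  states <- valve_state(seq, edges[-length(edges)])
  sum(diff(edges)[states])
}

#' Pseudorandom Poisson-switched valve sequence
#'
#' Generates valve toggle times as a realization of a homogeneous Poisson
#' point process, the switching scheme used to produce reproducible
#' fluctuating odorant streams: inter-toggle intervals are drawn i.i.d. from
#' an exponential distribution with the given mean and truncated to the
#' sequence duration. The default mean interval of 50 ms over a 10 s segment
#' matches the fluctuating-stimulus design.
#'
#' @param duration Sequence length in seconds (>= 0).
#' @param mean_interval Mean inter-toggle interval in seconds (> 0);
#'   the process rate is `1/mean_interval`.
#' @param seed Integer seed; identical arguments give bit-identical sequences.
#' @param channel Channel label forwarded to [valve_sequence()].
#' @return A [valve_sequence()] starting closed.
#' @export
poisson_valve_sequence <- function(duration, mean_interval, seed,
                                   channel = "A") {
  if (!is.numeric(mean_interval) || mean_interval <= 0) {
    stop("mean_interval must be positive")
  }
  stopifnot(duration >= 0)
  times <- local_seed(seed, {
    # draw in blocks until past the duration; exact exponential gaps
    acc <- numeric()
    last <- 0
    repeat {
      n <- max(16L, ceiling(1.5 * duration / mean_interval))
      gaps <- stats::rexp(n, rate = 1 / mean_interval)
      acc <- c(acc, last + cumsum(gaps))
      last <- acc[length(acc)]
      if (last >= duration) break
    }
    acc[acc < duration]
  })
  valve_sequence(times, duration = duration, channel = channel)
}
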