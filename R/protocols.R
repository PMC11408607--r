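#' Stimulus protocol for a two-channel odor stimulator
#'
#' A protocol bundles one [valve_sequence()] per odorant channel with the
#' concentration level and bookkeeping describing how the stimulus was
#' constructed. Times inside the valve sequences run in "trial time" from 0;
#' `t_origin` marks the moment of the leading (or pulse) valve opening, which
#' analysis treats as time zero.
#'
#' @param channels Named list with elements `A` and `B`, each a
#'   [valve_sequence()] of equal duration.
#' @param level Concentration level, `"low"` or `"high"`.
#' @param kind One of `"pulse"`, `"background_pulse"`, `"asynchrony_pair"`,
#'   `"fluctuating"`.
#' @param onset_asynchrony_ms Signed onset asynchrony in milliseconds
#'   (positive = A leads); only meaningful for `kind = "asynchrony_pair"`.
#' @param mixture_mode For fluctuating stimuli: `"A"`, `"B"`, `"AB_i"`,
#'   `"AB_A"`, `"AB_B"`; otherwise `"none"`.
#' @param t_origin Time of the analysis origin (leading/pulse valve opening)
#'   in trial time, seconds.
#' @param label Short stimulus identifier (e.g. `"A96B"`, `"AB_i"`).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(channels, level = c("low", "high"),
                              kind = c("pulse", "background_pulse",
                                       "asynchrony_pair", "fluctuating"),
                              onset_asynchrony_ms = NA_real_,
                              mixture_mode = "none",
                              t_origin = 0, label = NULL) {
  level <- match.arg(level)
  kind <- match.arg(kind)
  stopifnot(is.list(channels), setequal(names(channels), c("A", "B")),
            inherits(channels$A, "valve_sequence"),
            inherits(channels$B, "valve_sequence"))
  if (abs(channels$A$duration - channels$B$duration) > 1e-12) {
    stop("channel sequences must share one duration")
  }
  if (!is.na(onset_asynchrony_ms) && kind != "asynchrony_pair") {
    stop("onset_asynchrony_ms is only meaningful for asynchrony_pair protocols")
  }
  if (mixture_mode != "none" && kind != "fluctuating") {
    stop("mixture_mode is only meaningful for fluctuating protocols")
  }
  structure(
    list(channels = channels, level = level, kind = kind,
         onset_asynchrony_ms = onset_asynchrony_ms,
         mixture_mode = mixture_mode, t_origin = t_origin,
         duration = channels$A$duration,
         label = label %||% kind),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s (%s, %s level), %.3f s, t0 = %.3f s\n",
              x$label, x$kind, x$level, x$duration, x$t_origin))
  if (!is.na(x$onset_asynchrony_ms)) {
    cat(sprintf("  onset asynchrony: %+g ms (positive = A leads)\n",
                x$onset_asynchrony_ms))
  }
  if (x$mixture_mode != "none") cat("  mixture mode:", x$mixture_mode, "\n")
  invisible(x)
}

# one square opening [t_open, t_close) inside trial time
square_valve <- function(t_open, t_close, duration, channel) {
  stopifnot(t_close > t_open)
  valve_sequence(c(t_open, t_close), duration = duration, channel = channel)
}

closed_valve <- function(duration, channel) {
  valve_sequence(numeric(), duration = duration, channel = channel)
}

#' Single square odorant pulse
#'
#' One channel opens at the analysis origin for `pulse_duration`; the other
#' channel stays closed. This is the cognate-alone reference stimulus of the
#' onset-asynchrony experiments (0.5 s pulses by default).
#'
#' @param channel `"A"` or `"B"`.
#' @param pulse_duration Pulse length in seconds (> 0).
#' @param level Concentration level.
#' @param t_pre Baseline time before valve opening, seconds.
#' @param t_post Time after valve closing, seconds.
#' @return A [stimulus_protocol()] of kind `"pulse"`.
#' @export
make_pulse_protocol <- function(channel = c("A", "B"), pulse_duration = 0.5,
                                level = c("low", "high"),
                                t_pre = 0.5, t_post = 0.8) {
  channel <- match.arg(channel)
  level <- match.arg(level)
  if (!is.numeric(pulse_duration) || pulse_duration <= 0) {
    stop("pulse_duration must be positive")
  }
  dur <- t_pre + pulse_duration + t_post
  open_seq <- square_valve(t_pre, t_pre + pulse_duration, dur, channel)
  other <- setdiff(c("A", "B"), channel)
  chans <- list(open_seq, closed_valve(dur, other))
  names(chans) <- c(channel, other)
  stimulus_protocol(chans[c("A", "B")], level = level, kind = "pulse",
                    t_origin = t_pre, label = channel)
}

#' Onset-asynchrony pulse pair
#'
#' Both channels deliver equal square pulses; the leading channel opens at the
#' analysis origin and the trailing one `dt_ms` later. The experimental grid
#' uses asynchronies of 0, 3, 6, 12, 24, 48, or 96 ms with either odorant
#' trailing; labels follow the \eqn{A\Delta tB} convention (e.g. `"A96B"`
#' means A leads B by 96 ms).
#'
#' @param dt_ms Onset asynchrony in milliseconds (>= 0).
#' @param leading `"A"` or `"B"`; ignored distinction at `dt_ms = 0`.
#' @param pulse_duration Pulse length in seconds.
#' @param level Concentration level.
#' @param t_pre,t_post Baseline and tail time, seconds.
#' @return A [stimulus_protocol()] of kind `"asynchrony_pair"` whose
#'   `onset_asynchrony_ms` is signed: positive when A leads.
#' @export
make_asynchrony_protocol <- function(dt_ms, leading = c("A", "B"),
                                     pulse_duration = 0.5,
                                     level = c("low", "high"),
                                     t_pre = 0.5, t_post = 0.8) {
  leading <- match.arg(leading)
  level <- match.arg(level)
  if (!is.numeric(dt_ms) || dt_ms < 0) stop("dt_ms must be non-negative")
  dt <- dt_ms / 1000
  dur <- t_pre + dt + pulse_duration + t_post
  trailing <- setdiff(c("A", "B"), leading)
  lead_seq <- square_valve(t_pre, t_pre + pulse_duration, dur, leading)
  trail_seq <- square_valve(t_pre + dt, t_pre + dt + pulse_duration, dur,
                            trailing)
  chans <- list(lead_seq, trail_seq)
  names(chans) <- c(leading, trailing)
  label <- if (dt_ms == 0) "AB_sync" else
    paste0(leading, format(dt_ms, trim = TRUE), trailing)
  signed <- if (dt_ms == 0) 0 else if (leading == "A") dt_ms else -dt_ms
  stimulus_protocol(chans[c("A", "B")], level = level,
                    kind = "asynchrony_pair", onset_asynchrony_ms = signed,
                    t_origin = t_pre, label = label)
}

#' Pulse on a sustained odorant background
#'
#' A constant background odorant is switched on `background_lead` seconds
#' before a brief pulse of the other odorant; time zero is the opening of the
#' pulse valve. The background must lead by at least 2 s so that the
#' background-driven neuron is measured in its sustained response phase.
#'
#' @param background_channel,pulse_channel `"A"` or `"B"`, distinct.
#' @param background_lead Background head start in seconds (>= 2).
#' @param pulse_duration Pulse length in seconds.
#' @param level Concentration level.
#' @param t_pre Baseline before the background valve opens, seconds.
#' @param t_post Time after the pulse closes (background stays open), seconds.
#' @return A [stimulus_protocol()] of kind `"background_pulse"`.
#' @export
make_background_pulse_protocol <- function(background_channel, pulse_channel,
                                           background_lead = 2,
                                           pulse_duration = 0.5,
                                           level = c("low", "high"),
                                           t_pre = 0.5, t_post = 0.8) {
  level <- match.arg(level)
  stopifnot(background_channel %in% c("A", "B"),
            pulse_channel %in% c("A", "B"),
            background_channel != pulse_channel)
  if (background_lead < 2) {
    stop("background_lead must be >= 2 s (sustained-response phase)")
  }
  t0 <- t_pre + background_lead          # pulse valve opening
  dur <- t0 + pulse_duration + t_post
  bg <- valve_sequence(t_pre, duration = dur, channel = background_channel)
  pulse <- square_valve(t0, t0 + pulse_duration, dur, pulse_channel)
  chans <- list(bg, pulse)
  names(chans) <- c(background_channel, pulse_channel)
  stimulus_protocol(chans[c("A", "B")], level = level,
                    kind = "background_pulse", t_origin = t0,
                    label = paste(pulse_channel, "on", background_channel))
}

#' Correlated and uncorrelated fluctuating mixture set
#'
#' Builds the five fluctuating stimuli from exactly two Poisson-switched base
#' sequences: single odorants `A` and `B` (each following its own sequence),
#' the uncorrelated mixture `AB_i` (A follows sequence A, B follows sequence
#' B), and the correlated mixtures `AB_A` and `AB_B` in which both odorants
#' follow the identical time course of A or of B. All five share the same
#' total valve-open time per underlying sequence, so overall delivered
#' odorant amounts are matched across modes.
#'
#' @param duration Fluctuating segment length in seconds (default 10).
#' @param mean_interval Mean Poisson switching interval in seconds
#'   (default 0.05).
#' @param seedA,seedB Distinct integer seeds for the two base sequences.
#' @param level Concentration level.
#' @param t_pre Baseline before the segment, seconds.
#' @return Named list of five [stimulus_protocol()]s:
#'   `A`, `B`, `AB_i`, `AB_A`, `AB_B`.
#' @export
make_fluctuating_mixture_set <- function(duration = 10, mean_interval = 0.05,
                                         seedA, seedB,
                                         level = c("low", "high"),
                                         t_pre = 0.5) {
  level <- match.arg(level)
  if (identical(as.integer(seedA), as.integer(seedB))) {
    stop("seedA and seedB must differ (otherwise AB_i degenerates to AB_A)")
  }
  base_A <- poisson_valve_sequence(duration, mean_interval, seedA, "A")
  base_B <- poisson_valve_sequence(duration, mean_interval, seedB, "B")
  dur <- t_pre + duration

  shift <- function(base, channel) {
    valve_sequence(base$toggle_times + t_pre, duration = dur,
                   channel = channel)
  }
  proto <- function(chA, chB, mode) {
    stimulus_protocol(list(A = chA, B = chB), level = level,
                      kind = "fluctuating", mixture_mode = mode,
                      t_origin = t_pre, label = mode)
  }
  list(
    A    = proto(shift(base_A, "A"), closed_valve(dur, "B"), "A"),
    B    = proto(closed_valve(dur, "A"), shift(base_B, "B"), "B"),
    AB_i = proto(shift(base_A, "A"), shift(base_B, "B"), "AB_i"),
    AB_A = proto(shift(base_A, "A"), shift(base_A, "B"), "AB_A"),
    AB_B = proto(shift(base_B, "A"), shift(base_B, "B"), "AB_B")
  )
}

#' Export / import a stimulus protocol as JSON
#'
#' @param protocol A [stimulus_protocol()].
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `protocol_to_json()` returns the path (or JSON string) invisibly;
#'   `protocol_from_json()` returns a [stimulus_protocol()].
#' @export
protocol_to_json <- function(protocol, path = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  obj <- list(
    kind = protocol$kind,
    level = protocol$level,
    label = protocol$label,
    onset_asynchrony_ms = protocol$onset_asynchrony_ms,
    mixture_mode = protocol$mixture_mode,
    t_origin_s = protocol$t_origin,
    channels = lapply(c("A", "B"), function(ch) {
      vs <- protocol$channels[[ch]]
      list(channel = ch, initial_state = vs$initial_state,
           toggle_times_s = vs$toggle_times, duration_s = vs$duration)
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' @rdname protocol_to_json
#' @param x Path to a JSON file or a JSON string.
#' @export
protocol_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  chans <- lapply(seq_len(nrow(obj$channels)), function(i) {
    row <- obj$channels[i, ]
    valve_sequence(unlist(row$toggle_times_s),
                   duration = row$duration_s,
                   initial_state = row$initial_state,
                   channel = row$channel)
  })
  names(chans) <- obj$channels$channel
  stimulus_protocol(chans[c("A", "B")], level = obj$level, kind = obj$kind,
                    onset_asynchrony_ms = obj$onset_asynchrony_ms %||% NA_real_,
                    mixture_mode = obj$mixture_mode %||% "none",
                    t_origin = obj$t_origin_s, label = obj$label)
}
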