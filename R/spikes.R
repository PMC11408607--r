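#' Labeled spike train
#'
#' @param times Sorted spike times in seconds (analysis time, t = 0 at the
#'   leading valve opening; baseline spikes have negative times).
#' @param unit `"A"` or `"B"`.
#' @param fly_id,stimulus_id,trial_index Optional trial metadata.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit = NA_character_, fly_id = NA,
                        stimulus_id = NA_character_, trial_index = NA) {
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("spike times must be sorted")
  structure(list(times = times, unit = unit, fly_id = fly_id,
                 stimulus_id = stimulus_id, trial_index = trial_index),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s, %d spikes", x$unit, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Stochastic spikes from a drive trace
#'
#' Realizes an inhomogeneous Poisson process with intensity given by the
#' drive, then imposes an absolute refractory period by sequentially deleting
#' events closer than `refractory` to the previously accepted one (a
#' dead-time renewal process). Candidate events are generated by thinning a
#' homogeneous process at the drive maximum, so the pre-refractory process is
#' exact. For a constant drive `r` the realized rate is `r / (1 + r * refractory)`.
#'
#' @param drive A [drive_trace()] (values >= 0).
#' @param refractory Absolute refractory period in seconds (> 0).
#' @param seed Integer seed; identical inputs give identical trains.
#' @param unit,fly_id,stimulus_id,trial_index Metadata for the returned train.
#' @return A [spike_train()] in analysis time (drive `t0` subtracted).
#' @export
generate_spikes <- function(drive, refractory, seed, unit = NA_character_,
                            fly_id = NA, stimulus_id = NA_character_,
                            trial_index = NA) {
  stopifnot(inherits(drive, "drive_trace"), refractory > 0)
  r <- drive$values
  sr <- drive$sampling_rate
  duration <- length(r) / sr
  rmax <- max(r)
  times <- local_seed(seed, {
    if (rmax <= 0 || duration <= 0) {
      numeric()
    } else {
      n_cand <- stats::rpois(1, rmax * duration)
      cand <- sort(stats::runif(n_cand, 0, duration))
      # intensity at candidate times, piecewise-constant over samples
      idx <- pmin(floor(cand * sr) + 1L, length(r))
      keep <- stats::runif(n_cand) < r[idx] / rmax
      accepted <- cand[keep]
      enforce_refractory(accepted, refractory)
    }
  })
  spike_train(times - drive$t0, unit = unit, fly_id = fly_id,
              stimulus_id = stimulus_id, trial_index = trial_index)
}

# sequentially drop events within `refractory` of the last kept one
enforce_refractory <- function(times, refractory) {
  if (length(times) < 2L) return(times)
  keep <- logical(length(times))
  keep[1L] <- TRUE
  last <- times[1L]
  for (i in 2L:length(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}
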