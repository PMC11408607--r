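#' Parameters of a single olfactory receptor neuron
#'
#' Phenomenological transduction model: odorant concentration is mapped to an
#' intended instantaneous firing rate ("drive") through a Hill function whose
#' output is attenuated by a single first-order adaptation state. This gives
#' the canonical ORN response shape — a transient peak on a concentration
#' rise that relaxes to a lower sustained plateau. The defaults are
#' calibrated so that a 0.5-s cognate pulse at low concentration (1.43e-6)
#' yields a transient peak of roughly 70-75 spikes/s and a sustained rate of
#' roughly 21-25 spikes/s two seconds into a constant stimulus, with the
#' high-concentration (1.43e-3) counterparts near 120-230 and 35-52 spikes/s.
#'
#' @param baseline_rate Spontaneous rate, spikes/s.
#' @param max_rate Saturating suprabaseline drive, spikes/s.
#' @param half_conc Hill half-activation concentration (fraction).
#' @param hill_n Hill exponent.
#' @param adapt_tau Adaptation time constant, seconds.
#' @param adapt_strength Fraction of the activated drive removed at
#'   steady state, in `[0, 1]`.
#' @param adapt_half Activation level at which adaptation reaches half its
#'   asymptotic depth (makes adaptation depth weakly concentration-dependent).
#' @param refractory Absolute refractory period, seconds (> 0).
#' @param spike_amplitude Extracellular spike peak amplitude at rest, mV.
#' @param spike_width Biphasic spike width, ms.
#' @param amp_rate_decay Exponential decline of spike amplitude per unit of
#'   local firing rate, 1/(spikes/s).
#' @return An object of class `orn_params`.
#' @export
orn_params <- function(baseline_rate = 2, max_rate = 700,
                       half_conc = 2e-6, hill_n = 1,
                       adapt_tau = 0.06, adapt_strength = 0.97,
                       adapt_half = 0.02, refractory = 0.002,
                       spike_amplitude = 1.2, spike_width = 2.0,
                       amp_rate_decay = 0.004) {
  stopifnot(baseline_rate >= 0, max_rate >= 0, half_conc > 0, hill_n > 0,
            adapt_tau > 0, adapt_strength >= 0, adapt_strength <= 1,
            adapt_half > 0, refractory > 0, spike_amplitude > 0,
            spike_width > 0, amp_rate_decay >= 0)
  structure(as.list(environment()), class = "orn_params")
}

#' Parameters of a two-neuron sensillum
#'
#' Bundles the two ORN parameter sets with the ephaptic coupling gains and
#' recording-emulation settings. Coupling is reciprocal but asymmetric: the
#' large A neuron suppresses the small B neuron more strongly than the
#' converse (`g_AB >= g_BA`), matching the reported direction of the
#' asymmetry. The default B neuron has a three-fold smaller spike amplitude
#' than A.
#'
#' @param ornA,ornB [orn_params()] for the A (large) and B (small) neuron.
#' @param g_AB Coupling gain of A suppressing B (dimensionless).
#' @param g_BA Coupling gain of B suppressing A.
#' @param coupling_x50 Suprabaseline drive (spikes/s) at which the coupling
#'   gate is half-open; see [ephaptic_couple()].
#' @param coupling_hill Hill exponent of the coupling gate.
#' @param noise_sd Recording noise SD, mV.
#' @param sampling_rate Voltage-trace sampling rate, Hz.
#' @param drive_rate Sampling rate of concentration/drive traces, Hz.
#' @param fly_jitter_cv Lognormal coefficient of variation applied to
#'   per-fly parameter jitter in [simulate_experiment()].
#' @param trial_gain_cv Stationary lognormal coefficient of variation of a
#'   slowly varying response gain shared by both neurons, emulating the slow
#'   state and recording-quality fluctuations that dominate trial-to-trial
#'   variability in sensillum recordings beyond spike-count noise. The gain
#'   is an Ornstein-Uhlenbeck process in log space, so it is approximately
#'   constant within a sub-second trial but decorrelates over long trials.
#' @param trial_gain_tau Correlation time of the gain process, seconds.
#' @param conc_peaks Named numeric, steady-state concentration fraction by
#'   level; defaults pin the printed dilutions 1.43e-3 (high) and 1.43e-6
#'   (low).
#' @param tau_rise,tau_fall Valve-to-concentration filter constants, seconds.
#' @return An object of class `sensillum_params`.
#' @export
sensillum_params <- function(ornA = orn_params(),
                             ornB = orn_params(spike_amplitude = 0.4,
                                               spike_width = 1.5),
                             g_AB = 0.6, g_BA = 0.24,
                             coupling_x50 = 70, coupling_hill = 5,
                             noise_sd = 0.03, sampling_rate = 10000,
                             drive_rate = 1000, fly_jitter_cv = 0.1,
                             trial_gain_cv = 0.25, trial_gain_tau = 2,
                             conc_peaks = c(low = 1.43e-6, high = 1.43e-3),
                             tau_rise = 0.010, tau_fall = 0.012) {
  stopifnot(inherits(ornA, "orn_params"), inherits(ornB, "orn_params"),
            g_AB >= 0, g_BA >= 0, coupling_x50 > 0, coupling_hill > 0,
            noise_sd >= 0, sampling_rate > 0,
            drive_rate > 0, fly_jitter_cv >= 0, trial_gain_cv >= 0,
            trial_gain_tau > 0,
            all(c("low", "high") %in% names(conc_peaks)))
  structure(as.list(environment()), class = "sensillum_params")
}

#' Latent firing-rate drive trace
#'
#' @param values Intended instantaneous firing rate per sample, spikes/s
#'   (>= 0).
#' @param sampling_rate Hz.
#' @param t0 Analysis origin, seconds from the first sample.
#' @return An object of class `drive_trace`.
#' @export
drive_trace <- function(values, sampling_rate, t0 = 0) {
  stopifnot(sampling_rate > 0, all(values >= 0))
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
                 t0 = t0),
            class = "drive_trace")
}

#' @export
print.drive_trace <- function(x, ...) {
  cat(sprintf("<drive_trace> %d samples @ %g Hz, peak %.1f spikes/s\n",
              length(x$values), x$sampling_rate, max(x$values)))
  invisible(x)
}

#' Odorant transduction with adaptation
#'
#' Maps a concentration trace to an ORN's intended firing rate. For the
#' cognate odorant the activation is `H(c) = c^n / (c^n + K^n)` and the drive
#' is `baseline + max_rate * H * (1 - a)`, where the adaptation state `a`
#' relaxes with time constant `adapt_tau` toward
#' `adapt_strength * H / (H + adapt_half)`. An incognate odorant does not
#' activate the neuron at all, so the drive stays at baseline.
#'
#' @param conc A [concentration_trace()].
#' @param p An [orn_params()].
#' @param cognate Does this odorant activate the neuron?
#' @return A [drive_trace()] at the concentration trace's sampling rate.
#' @export
transduce <- function(conc, p, cognate = TRUE) {
  stopifnot(inherits(conc, "concentration_trace"), inherits(p, "orn_params"))
  n <- length(conc$values)
  if (!cognate) {
    return(drive_trace(rep(p$baseline_rate, n), conc$sampling_rate, conc$t0))
  }
  cn <- conc$values^p$hill_n
  H <- cn / (cn + p$half_conc^p$hill_n)
  a_inf <- p$adapt_strength * H / (H + p$adapt_half)
  k <- 1 - exp(-1 / (conc$sampling_rate * p$adapt_tau))
  a <- stats::filter(k * a_inf, 1 - k, method = "recursive")
  drive <- p$baseline_rate + p$max_rate * H * (1 - as.numeric(a))
  drive_trace(pmax(drive, 0), conc$sampling_rate, conc$t0)
}

#' Instantaneous subtractive ephaptic coupling
#'
#' Each neuron's drive is reduced, sample-synchronously, by a gated
#' subtractive function of its neighbour's suprabaseline drive, with
#' rectification at zero. Both coupled drives are computed from the
#' *uncoupled* inputs (no fixed-point iteration):
#' \deqn{B'(t) = \max(0,\; B(t) - g_{AB}\, w(x_A(t))\, x_A(t)),\qquad
#'       w(x) = \frac{x^h}{x^h + x_{50}^h}}
#' (and symmetrically for A, with gain \eqn{g_{BA}}), where
#' \eqn{x_A = \max(0, A - b_A)} is A's drive above its baseline rate. The
#' sigmoid gate `w` makes the coupling effectively linear-subtractive for
#' strong transient drives but negligible for weak residual activity: a
#' neuron's onset transient suppresses its neighbour strongly, while the
#' low adapted tail of a response that started tens of milliseconds earlier
#' does not. This expansive drive-dependence is what confines measurable
#' inhibition to near-synchronous onsets and makes inhibition strength grow
#' with concentration. The coupling has zero latency, consistent with fast,
#' temporally precise ephaptic interaction.
#'
#' @param driveA,driveB Uncoupled [drive_trace()]s of equal length and rate.
#' @param s A [sensillum_params()] providing the gains, the gate parameters
#'   and the baselines.
#' @return List with coupled drive traces `A` and `B`.
#' @export
ephaptic_couple <- function(driveA, driveB, s) {
  stopifnot(inherits(driveA, "drive_trace"), inherits(driveB, "drive_trace"),
            inherits(s, "sensillum_params"))
  if (length(driveA$values) != length(driveB$values) ||
      driveA$sampling_rate != driveB$sampling_rate) {
    stop("drives must share length and sampling rate")
  }
  gate <- function(x) {
    xh <- x^s$coupling_hill
    xh / (xh + s$coupling_x50^s$coupling_hill)
  }
  supraA <- pmax(driveA$values - s$ornA$baseline_rate, 0)
  supraB <- pmax(driveB$values - s$ornB$baseline_rate, 0)
  newA <- pmax(driveA$values - s$g_BA * gate(supraB) * supraB, 0)
  newB <- pmax(driveB$values - s$g_AB * gate(supraA) * supraA, 0)
  list(A = drive_trace(newA, driveA$sampling_rate, driveA$t0),
       B = drive_trace(newB, driveB$sampling_rate, driveB$t0))
}
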