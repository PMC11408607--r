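---
title: "Models and methods: onset timing and ephaptic inhibition in a two-neuron sensillum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: onset timing and ephaptic inhibition in a two-neuron sensillum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensillum)
```

## What this package models

A *Drosophila* ab3 sensillum houses two olfactory receptor neurons: the
large-spiking ab3A (cognate odorant: methyl hexanoate, channel "A") and the
small-spiking ab3B (cognate odorant: 2-heptanone, channel "B"). Because both
neurons share one electrically insulated lymph space, each suppresses the
other's firing nonsynaptically (ephaptic inhibition). The scientific question
the package addresses is *temporal*: how does the strength of that mutual
inhibition depend on the relative timing of the two odorants' onsets, and on
the correlation between two fluctuating odorant streams?

The package provides the full chain needed to study this question on
synthetic data: a stimulus designer mirroring a two-channel valve stimulator,
a phenomenological two-neuron simulator, an amplitude-based two-unit spike
sorter, causal firing-rate estimation, an exact Victor–Purpura spike-train
distance, and the statistical battery (paired and FDR-corrected t tests,
per-fly regressions, U tests with Bonferroni correction, synchrony-window
estimation).

## Stimulus design

Valve command sequences are stored as toggle times plus an initial state, so
the valve state is exact at any sampling rate; dense traces are derived
views. Fluctuating stimuli switch the valves at the points of a homogeneous
Poisson process (mean interval 50 ms over a 10-s segment), realized by exact
exponential inter-event sampling truncated at the segment end. The five
fluctuating stimuli are built from exactly two base sequences: single
odorants A and B, the uncorrelated mixture AB\_i (each channel follows its
own sequence), and the correlated mixtures AB\_A and AB\_B (both channels
follow one sequence), so the total valve-open time is matched across modes.

Concentration traces emulate a photoionization detector: a first-order
low-pass of the binary valve state with asymmetric time constants, scaled to
the level's steady-state dilution. The air-dilution arithmetic reproduces
the stimulator's printed figures (one 3:297 mL/min stage per channel, two
channels combined into a 1.5 L/min carrier gives a total outlet flow of
2.1 L/min and a high-concentration dilution of 1.43e-3). The published
description of the low-concentration serial dilution does not arithmetically
yield the printed 1.43e-6 (three 1:100 stages would give 1.43e-7), so the
level presets pin the final fractions to the printed values and the
stage arithmetic remains available separately through `compute_air_dilution()`.

Time zero of every analysis is the opening of the leading (or pulsed) valve.
All quantification windows are half-open `[a, b)` and in seconds.

### PID dynamics

Defaults are `tau_rise = 10` ms and `tau_fall = 12` ms. The stimulator the
package emulates was engineered for maximal concentration rise speed; the
rise constant matters scientifically because the inhibited neuron's response
peak must occur within 96 ms of valve opening (with slower rise constants
the kernel-smoothed peak drifts past the largest onset asynchrony of the
design, which would confound the timing analysis). Both constants are
configurable on `sensillum_params()`.

## The two-neuron simulator

### Transduction

Concentration is mapped to an intended instantaneous firing rate ("drive")
through a Hill activation `H(c) = c^n / (c^n + K^n)` whose output is
attenuated by one first-order adaptation state:

$$r(t) = r_0 + r_\max\, H(c(t))\, (1 - a(t)), \qquad
\tau_a \dot a = s\,\frac{H}{H + h_a} - a$$

with spontaneous rate `r_0`, saturating gain `r_max`, adaptation time
constant `tau_a`, depth `s`, and a weak concentration dependence of the
adaptation depth through `h_a`. An incognate odorant does not activate the
neuron at all, so its drive stays at `r_0`.

Defaults are calibrated against the published firing-rate anchors: a 0.5-s
cognate pulse at the low dilution (1.43e-6) gives a measured (alpha-kernel)
transient peak of about 73 spikes/s and a sustained rate of about 23
spikes/s in a window starting 2 s into a constant stimulus; at the high
dilution (1.43e-3) the same quantities are about 132 and 35 spikes/s. The
Hill pair (`hill_n = 1`, `half_conc = 2e-6`) reproduces the roughly two-fold
peak ratio between the two dilutions while letting concentration troughs in
fluctuating stimuli genuinely silence the drive — a shallow Hill exponent
would keep the neuron saturated at the high dilution throughout the
fluctuating segment, which suppresses the correlation-dependent effects the
experiments measure.

### Ephaptic coupling

Coupling is instantaneous (zero latency), reciprocal, asymmetric, and
subtractive on the latent drives, computed from the uncoupled drives without
fixed-point iteration:

$$B'(t) = \max\!\big(0,\; B(t) - g_{AB}\, w(x_A)\, x_A\big), \qquad
w(x) = \frac{x^h}{x^h + x_{50}^h},$$

where `x_A` is A's drive above its spontaneous rate (and symmetrically for
A with gain `g_BA < g_AB`). The sigmoid gate `w` is the package's central
phenomenological choice. A purely linear subtractive rule cannot reproduce
the published timing selectivity: with gains large enough to give the
observed 35–50% suppression at synchronous onsets, the inhibitor's adapted
post-transient drive (about 20 spikes/s above baseline) still suppresses the
partner by 10–15% at 96 ms onset asynchrony, which at the design size
(8 flies x 10 trials) is always statistically significant and widens the
synchrony window to 144–192 ms. Gating the subtraction by the inhibitor's
own drive makes inhibition effectively linear for strong transients and
negligible for weak residual activity, which is also what confines
measurable inhibition to near-synchronous onsets (a 48-ms-old transient is
still ~85 spikes/s above baseline and inhibits; a 96-ms-old one has decayed
to ~50 and barely does) and what makes inhibition strength grow with
concentration. The same gate produces the correlation effect for fluctuating
stimuli: when the two streams are correlated, the inhibitor is strong
exactly when the inhibited neuron is active, whereas uncorrelated inhibition
often arrives while the partner has little activity to suppress and is
partially wasted by the rectification at zero.

### Spiking and variability

Spike times are an inhomogeneous Poisson process (exact thinning of a
homogeneous process at the drive maximum) with an absolute refractory period
imposed as a dead time; for a constant drive `r` the realized rate is
`r / (1 + r * refractory)`. Two additional sources of variability emulate a
real multi-fly data set:

* per fly, response gains, spike amplitudes, and coupling gains are jittered
  multiplicatively (lognormal, CV `fly_jitter_cv = 0.1`);
* per trial, both neurons share a slowly varying response gain — a lognormal
  Ornstein–Uhlenbeck process with stationary CV `trial_gain_cv = 0.25` and
  correlation time 2 s. This reproduces the large per-stimulus trial spread
  visible in real single-sensillum box plots: it is essentially a constant
  gain within a 0.5-s pulse trial but decorrelates across a 10-s fluctuating
  trial, so long-trial spike counts are not dominated by whole-trial offsets.

Seeding is hierarchical (experiment, fly, trial), so enlarging a design does
not perturb the trials already simulated.

### Voltage traces

Each spike adds a biphasic (one-cycle sine) waveform, 2 ms wide and 1.2 mV
for A, 1.5 ms and 0.4 mV for B, with the template peak aligned to the spike
time. The per-spike amplitude declines exponentially with the unit's local
firing rate (causal exponential window, time constant 100 ms), the
characteristic spike-shape change of sensillum recordings during bursts.
White Gaussian noise (SD 0.03 mV) is added, and the ground-truth event list
is retained on the trace.

### What the generator does and does not emulate

It emulates: two spike-amplitude classes with rate-dependent amplitude
decline; asymmetric, concentration-dependent, onset-timing-sensitive mutual
suppression; fly-to-fly and trial-to-trial gain variability; trial
structures of the three experimental designs. It does not emulate: the
biophysics of the transepithelial circuit; receptor kinetics; spike-waveform
drift, electrode artifacts, or field potentials; more than two neurons; or
non-Poisson spike-timing reliability (real ORN trains are more precisely
time-locked to frozen stimuli than Poisson realizations, so absolute
Victor–Purpura distances here have a higher noise floor than real data, and
only orderings between stimulus pairs are meaningful). Passing tests
therefore demonstrate that the analysis chain recovers the effects this
model family produces at realistic noise levels — not that it would recover
them from any particular real recording.

## Spike sorting

Detection band-passes the trace (zero-phase Butterworth, defaults 10–4000 Hz
at the 10-kHz trace rate), finds local maxima above `threshold_mads` times
the median absolute deviation, and enforces a minimum event spacing of half
the narrowest spike width. Sorting then iterates a hard EM built on a single
premise — spike amplitude declines with the unit's firing rate: labels are
initialized by a deterministic Otsu split on peak amplitude; each iteration
estimates every unit's local rate at every event (causal exponential
window), fits a monotone non-increasing exponential amplitude-versus-rate
curve per unit, and reassigns each event to the unit whose predicted
amplitude is nearest in units of that unit's residual scale, with per-unit
refractoriness enforced. The larger-amplitude cluster is named "A".

Two safeguards matter in practice. First, if the converged two-unit fit does
not reduce the pooled residual scale below 0.7 of a single amplitude–rate
curve fitted to all events, the amplitude variation is explained by rate
alone and the sorter returns a flagged single unit (splitting a unimodal
cloud in half reduces its residual scale to about 0.6, a genuine mixture to
far less). Second, coincident spikes: when both units fire within one
detection window, the event is absorbed by the larger unit. Absorption alone
systematically deletes B spikes exactly when A is co-active, which inflates
apparent mixture suppression downstream; the sorter therefore emits an
additional B spike for any A event whose peak or trough deviates from the
amplitude-model prediction by more than half the predicted B amplitude.
This recovers superpositions without any waveform re-detection; B spikes
cancelled inside A's negative lobe remain unrecoverable, leaving a residual
loss of about 3% of B spikes during strongly coincident transients — an
inherent limitation of amplitude-only sorting, and the reason the
sorted-versus-ground-truth comparison in the test suite tolerates flips of
knife-edge significance calls while requiring every decisive call to agree.

When a whole trial table is sorted (`sort_trial_table()`), all trials of a
fly are detected separately but sorted jointly, as one recording session
with a shared amplitude model; this keeps single-odorant trials (where one
unit is nearly silent) correctly labeled.

## Spike-train metrics

Firing rates are estimated by convolving spike trains with a causal alpha
kernel `k(t) = (t/τ²) e^{-t/τ}` for `t ≥ 0`, discretized and renormalized to
unit mass. The published "standard width σ = 50 ms" is interpreted as the
time constant τ (the kernel then peaks 50 ms after each spike); interpreting
σ as the kernel's standard deviation instead would correspond to
`sigma = 0.050 / sqrt(2)` and is available by passing that value.

Single-trial response peak rates are read out, by default, at the argmax of
the fly's trial-averaged rate for that stimulus (`peak_readout =
"mean_argmax"`). The alternative per-trial maximum is biased upward by
whichever part of the search window has elevated rate — with 10 trials per
stimulus that bias manufactured a spurious ~5% "suppression" at the largest
onset asynchrony, because the partner's late transient removed eligible
noise maxima from the window. The per-trial maximum remains available
(`"trial_max"`); the exact window used in the original figure is not
printed, so the default window is the first 0.5 s after the leading valve
opening.

The Victor–Purpura distance is computed by the standard exact dynamic
program in compiled code (insertions and deletions cost 1, shifts cost
`q |Δt|`). The cost factor used in the original analysis is not printed, so
quantitative distances are not reproducible and the package treats only
orderings as meaningful. The package default is `q = 20`/s — a shift beyond
2/q = 100 ms costs as much as delete-plus-insert, matching the 50-ms rate
kernel's temporal scale — and every distance output records `q`. Distances
for the fluctuating designs are computed over the full 10-s segment.

## Statistical pipeline

* Tests operate on per-fly means (n = number of flies), matching how the
  group sizes are reported in the original figures; trial-level mixed models
  are out of scope.
* The onset-asynchrony battery normalizes each trial by the same fly, unit
  and level's mean cognate-alone response, then runs two-tailed paired
  t tests of each mixture against cognate-alone per unit, with
  Benjamini–Hochberg correction within each unit's battery of 13 mixtures
  (the figure's stars are per-unit; the family is not stated in the source,
  and this choice is logged here as an assumption). All battery decisions
  are invariant to rescaling any fly's raw rates.
* The synchrony-window width is the largest significant |asynchrony| on the
  A-leading side plus the largest on the B-leading side, counting only
  suppressive (normalized mean < 1) effects.
* The pooled regression regresses the normalized response on |Δt|:
  responses recover as the onsets move apart, so inhibition growing with
  synchrony appears as a positive slope, matching the printed sign of the
  original average regression; one OLS line per fly over its trial values
  plus an average regression over all points.
* Victor–Purpura group comparisons pool within-fly cross-trial distances
  across flies (same-stimulus pairs are unordered and exclude self-pairs)
  and use two-sided Mann–Whitney U tests with Bonferroni correction across
  the listed comparisons.

## Design sizes and seeds used by the tests

The three presets encode the published designs: background-plus-pulse
(8 flies at low or 6 at high concentration, 3 trials), onset asynchrony
(15 stimuli, 8 flies, 10 trials, low concentration), and fluctuating
mixtures (5 stimuli of 10 s, 8 flies at high or 6 at low concentration,
5 trials). The acceptance checks run 20 replicates of the asynchrony preset
for the synchrony-window distribution, 100 coupling-off replicates for
type-I control, 4 sorted replicates for the end-to-end sorting comparison,
and 100-trial batches for the calibration anchors; these sizes give stable
verdicts for the quantities asserted while each check completes in minutes.

## Known limitations

* The coupling rule is phenomenological; the gate parameters (`x50`, `h`)
  are identified only up to the behavior they were calibrated to (synchrony
  window, concentration dependence, correlation effect), not by biophysics.
* Poisson spiking understates the timing reliability of real ORNs, so
  absolute distance values and distance noise floors differ from real data.
* Collisions of coincident spikes are only partially recoverable from
  amplitude features; about 3% of small-unit spikes are lost during strongly
  coincident transients, biasing mixture responses down by roughly 0.03 in
  normalized units.
* Knife-edge significance calls (adjusted p at the threshold) are not
  reproducible across any resampling, including between ground-truth
  redraws; end-to-end comparisons should only rely on decisive calls.
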