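# sensillum

Simulation and analysis of ephaptic inhibition between the two co-localized
olfactory receptor neurons (ORNs) of a *Drosophila* ab3 sensillum, and of how
that inhibition depends on the relative timing of odorant onsets.

## The problem

The ab3 sensillum houses two ORNs in one electrically insulated lymph space:
the large-spiking ab3A (cognate odorant methyl hexanoate, "A") and the
small-spiking ab3B (cognate odorant 2-heptanone, "B"). The two neurons
suppress each other nonsynaptically (ephaptic inhibition). In a turbulent
plume, odorants from one source arrive synchronously and odorants from
different sources arrive asynchronously — so if ephaptic inhibition is
strongest for synchronous onsets, it can help a fly decide whether two
odorants share a source. The analyses this package implements quantify
exactly that: how much the transient response of each ORN is suppressed as a
function of onset asynchrony (0, 3, 6, 12, 24, 48, 96 ms, either odorant
leading), of odorant concentration, and of the correlation between two
fluctuating odorant streams.

The package is built for synthetic data: it ships a full two-neuron
sensillum simulator so that every stage of the analysis chain can be
verified against ground truth. The pieces are:

* **Stimulus design** — two-channel valve sequences (square pulses,
  background-plus-pulse, onset-asynchrony pairs, Poisson-switched
  fluctuating mixtures with mean switching interval 50 ms), PID-like
  concentration traces, and the stimulator's air-dilution arithmetic.
* **Sensillum simulator** — Hill transduction with first-order adaptation,
  gated subtractive ephaptic coupling
  `B' = max(0, B − g_AB · w(x_A) · x_A)` with `w(x) = x^h / (x^h + x50^h)`,
  inhomogeneous-Poisson spiking with refractory dead time, per-fly and
  per-trial gain variability, and extracellular voltage synthesis with
  rate-dependent spike amplitudes.
* **Spike sorting** — amplitude-based two-unit sorter (Otsu initialization,
  hard EM over exponential amplitude-versus-rate curves, refractory
  enforcement, single-unit fallback, coincidence recovery) plus scoring
  against ground truth.
* **Spike-train metrics** — causal alpha-kernel rate estimation
  (`k(t) ∝ t·e^{−t/τ}`, τ = 50 ms), window rates, response peak rates, onset
  latency, and an exact Victor–Purpura distance (dynamic programming in
  compiled code; insert/delete cost 1, shift cost `q·|Δt|`).
* **Statistics** — paired t tests, cognate normalization, Benjamini–Hochberg
  FDR, the onset-asynchrony test battery, synchrony-window width, per-fly
  and pooled regressions, and Mann–Whitney U tests with Bonferroni
  correction for Victor–Purpura group comparisons.

## Worked example

Reproduce the onset-asynchrony experiment end to end (8 simulated flies,
15 stimuli, 10 trials each, low concentration):

```r
library(sensillum)

compute_air_dilution(flow_config())
#> $dilution_fraction
#> [1] 0.001428571
#> $total_flow
#> [1] 2.1

cfg <- run_config("fig3", seed = 1)
res <- run_experiment(cfg)
res
#> <run_result> fig3 (seed 1)
#> <trial_table> 8 flies x 15 stimuli x 10 trials (2400 trains, 50663 spikes)
#>   synchrony window width: 72 ms

b <- res$battery[res$battery$unit == "B", ]
b[order(b$onset_asynchrony_ms),
  c("stimulus_id", "onset_asynchrony_ms", "mean_normalized", "p_adjusted")]
#>  stimulus_id onset_asynchrony_ms mean_normalized p_adjusted
#>         B96A                 -96           1.040   5.18e-01
#>         B48A                 -48           0.697   9.32e-04
#>         B24A                 -24           0.581   1.46e-06
#>         B12A                 -12           0.555   6.30e-06
#>          B6A                  -6           0.584   2.19e-05
#>          B3A                  -3           0.612   6.82e-05
#>      AB_sync                   0           0.613   7.27e-06
#>          A3B                   3           0.627   5.75e-04
#>          A6B                   6           0.639   3.13e-05
#>         A12B                  12           0.661   7.95e-05
#>         A24B                  24           0.797   9.00e-03
#>         A48B                  48           0.934   2.59e-01
#>         A96B                  96           1.069   1.82e-01

res$regression
#> <regression_result> average slope 0.004852 per ms, r^2 = 0.226, p = 1.18e-59
#>   per-fly slopes: 8 flies, 8 with p < 0.05
```

Reading the output: ab3B's peak response to a synchronous mixture drops to
about 0.61 of its cognate-alone response, the suppression weakens
monotonically with onset asynchrony, and it is no longer significant at
96 ms with either odorant leading — a synchrony window of 72 ms here (the
largest significant asynchrony on each side, summed). The positive pooled
regression slope says responses recover as onsets move apart, i.e. ephaptic
inhibition grows with synchrony.

The other presets work the same way: `run_config("fig2", level = "high")`
(a pulse of one odorant into a sustained background of the other; paired
t tests of cognate-alone versus with-background window rates) and
`run_config("fig4")` (five 10-s fluctuating-mixture stimuli; within-fly
pairwise Victor–Purpura distances and U tests showing that a correlated
incognate stream distorts responses more than an uncorrelated one).

The methods vignette (`vignettes/ephaptic-timing-methods.Rmd`) documents the
model equations, the calibration of every default, and the package's
limitations.

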