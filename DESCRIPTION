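Package: sensillum
Title: Simulation and Analysis of Ephaptic Inhibition Between Co-Localized
    Olfactory Receptor Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the relative timing of odorant onsets
    modulates ephaptic (nonsynaptic) inhibition between the two olfactory
    receptor neurons of a Drosophila ab3 sensillum. Provides a stimulus
    designer (square pulses, background-plus-pulse, onset-asynchrony pairs,
    and Poisson-switched fluctuating binary mixtures with air-dilution
    arithmetic), a phenomenological two-neuron sensillum simulator with
    asymmetric subtractive coupling and rate-dependent extracellular spike
    amplitudes, an amplitude-based two-unit spike sorter, causal alpha-kernel
    firing-rate estimation, an exact Victor-Purpura spike-train distance, and
    the statistical pipeline (paired and FDR-corrected t tests, per-fly and
    pooled regressions, Mann-Whitney U tests with Bonferroni correction,
    synchrony-window estimation) used to quantify onset-asynchrony effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
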