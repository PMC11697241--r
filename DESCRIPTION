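Package: spikerel
Title: Spike-Timing Reliability Analysis of Frozen-Noise Current-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-neuron spike-timing reliability from
    repeated frozen-noise current-clamp sweeps. Generates the sum-of-sines pink
    noise stimulation protocol (1-100 Hz, CV 0.2, three concatenated 1 s
    templates scaled to 75/100/150 percent rheobase), computes matching-spike
    reliability in a coincidence window with a firing-rate permutation
    correction, nearest-spike latency distributions and subthreshold voltage
    reliability, classifies cells as fast or regular spiking from the averaged
    action-potential half-width, and simulates a downstream Izhikevich neuron
    driven by jittered excitatory or inhibitory input populations. A synthetic
    sweep generator with controllable jitter provides populations with known
    reliability structure for parameter-recovery testing, plus group-level
    statistics (Kruskal-Wallis, pairwise Kolmogorov-Smirnov, rank correlations
    with intrinsic features, two-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
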