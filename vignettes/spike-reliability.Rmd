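---
title: "Measuring spike-timing reliability from frozen-noise sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spike-timing reliability from frozen-noise sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A neuron injected repeatedly with an identical ("frozen") noise current
does not repeat its spike train exactly. Two nuisances confound any naive
coincidence count between repetitions: the firing rate (a fast-firing cell
produces chance coincidences) and the trial count (metrics built from
pooled spike sets grow or shrink with the number of sweeps). The pipeline
in this package is built around a statistic designed to be robust to both,
so that cell classes recorded with different rates and different numbers
of repetitions remain comparable.

## The stimulation protocol

The frozen noise is a sum of sine waves, 1–100 Hz in 1 Hz steps, each at a
uniformly random phase with amplitude proportional to $1/\sqrt{f}$, which
yields $1/f$ ("pink") power — equal energy per octave, a standard proxy for
aggregate synaptic input. The 1 s template is mean-removed and rescaled so
that, relative to the unit DC offset added when the protocol is assembled,
its coefficient of variation is exactly 0.2. Three copies are concatenated
into a 3 s stimulus template; copies scaled to 75 %, 100 % and 150 % of
the cell's rheobase are delivered in increasing order with 5 s of zero
current between them.

Decisions the protocol description leaves open, and what we chose:

* **Sampling rate.** Not a protocol constant; default 25 kHz, configurable.
  Every structural invariant (CV, spectral slope, periodicity, scaling
  linearity) holds at any rate at least twice the top frequency, and the
  test suite exercises 500 Hz–25 kHz.
* **CV enforcement.** The $1/\sqrt{f}$ amplitudes fix only *relative*
  weights; the summed trace is rescaled so the sample SD equals
  `cv` exactly (CV is a stated property of the protocol, not an
  approximation). `stats::sd` (the $n-1$ denominator) is used; at
  $n \ge 500$ samples the distinction is far below any tolerance used.
* **Recovery placement.** Recovery windows separate segments only; leading
  and trailing padding are explicit arguments defaulting to zero.
* **Autocorrelation of a constant trace** is an error (zero variance), not
  an all-ones vector: silent NaN propagation would hide degenerate
  stimuli. The autocorrelation is FFT-based, mean-removed, normalized to
  1 at zero lag; the 3× concatenation shows up as a local maximum at a lag
  of one template duration.

## The reliability statistic

For an ordered pair of sweeps $(i, j)$, the directed matching fraction is
the share of spikes in sweep $i$ with at least one spike of sweep $j$
within $w = 1$ ms (inclusive boundary, $|\Delta t| \le w$; inclusivity is
stated because recorded spike times are fixed-point and ties can occur).
A neuron's raw reliability is the mean over *all ordered pairs* of usable
sweeps. Averaging ordered pairs (equivalently, both directions of each
unordered pair) preserves the per-spike interpretation when trains differ
in length, and makes the estimator's expectation independent of the
number of trials — more sweeps only reduce its variance. The test suite
verifies this unbiasedness by Monte Carlo rather than by duplicating
sweeps: literal duplicates would create identical-train pairs with
fraction 1 and do not represent additional trials.

Sweeps with zero spikes are excluded from pair formation (a 0/0 fraction
is undefined); the number excluded is recorded on the result. At least two
spiking sweeps are required, otherwise the computation refuses rather than
returning a silent NA.

**Firing-rate correction.** The raw value is compared against surrogates
in which each sweep keeps its spike count but its spike times are redrawn
uniformly within the stimulus window — our reading of "randomly permuted
within the stimulus time window" with counts preserved; an alternative
reading (permuting inter-spike intervals) preserves short-range structure
that the correction is precisely meant to remove, so we did not adopt it.
The corrected value is raw minus the surrogate mean over 100 permutations
(default). Permutation seeds derive deterministically from the caller's
seed, so results are reproducible and permutations are independent across
neurons.

**Aggregation.** Reliability is computed per (noise, intensity) sweep set
and averaged across the two noises per neuron; the analysis intensity
defaults to 100 % rheobase (150 % serves as a confirmation condition).
Latency pools for the cumulative-distribution displays combine both
noises.

## The synthetic population

The generator exists so that every downstream metric can be tested by
parameter recovery: ground truth is a per-segment inhomogeneous Poisson
train whose intensity follows the positive part of the stimulus, and each
sweep is that train with (a) each spike deleted with probability
`spike_deletion_prob`, (b) survivors shifted by Gaussian noise of SD
`jitter_sd_ms`, and (c) homogeneous extra spikes at `extra_spike_rate_hz`.
Jitter and deletion are therefore the *only* reliability knobs — a
deliberate departure from a biophysical generator, which would entangle
reliability with excitability.

Default class settings mirror the study conditions and the field's
qualitative knowledge: repetition counts uniform on 2–8 per noise;
PV-like cells with sub-millisecond jitter (0.2 ms), high rheobase
(220 pA), short membrane time constant (8 ms), narrow spikes (250 µs);
excitatory-like cells with 5 ms jitter, 90 pA, 25 ms, 550 µs; non-PV
inhibitory and mixed classes in between. Firing at 75 % rheobase is
scaled to 5 % of the 100 % rate (just below threshold) and 150 % to 160 %.
Intrinsic features are drawn lognormally around class-typical values
derived from the membrane time constant (upstroke/downstroke ratio
increasing in τ, ramp time decreasing, capacitance ∝ τ^0.7, conductance =
capacitance/τ), which embeds feature–reliability correlations with the
signs reported for cortex (reliability falling with τ and capacitance,
rising with rheobase, ramp time and conductance) without hard-coding any
correlation coefficient.

Optional voltage traces are a shared membrane-filtered copy of the
stimulus plus per-sweep AR(1) noise, mixed so a configurable fraction of
variance is shared across sweeps (making the expected pairwise rank
correlation tunable), plus stereotyped Gaussian action potentials of
class-specific width at the spike times.

What passing tests on this generator do **not** show: real sweeps have
adaptation, bursting, refractory structure, electrode drift and
non-stationary excitability; none of these are emulated, so recovery here
demonstrates correctness of the estimators, not their field performance on
arbitrary biology.

## Cell typing

The averaged spike's width at half amplitude uses linear interpolation
between samples on both flanks; the boundary at exactly 400 µs classifies
as *regular* ("fast" is strictly below). The baseline is an argument (the
pre-spike median over a short window is a reasonable choice) because no
single convention fits all recording configurations. The transgenic
line-to-group table ships as an editable CSV; unknown lines raise an
error naming the label instead of defaulting, because silently lumping an
unrecognized line into "mixed" would corrupt group comparisons.

## The downstream model

A regular-spiking Izhikevich neuron ($a=0.02$, $b=0.2$, $c=-65$, $d=8$;
voltage capped at 30 mV) integrates $dv/dt = 0.04v^2 + 5v + 140 - u + I$,
$du/dt = a(bv-u)$ with the model's original modified Euler scheme — $v$
advanced in two half-steps of $dt/2$ per $u$ update, $dt = 0.5$ ms. The
coefficients are configuration, not conclusions: the parameter-robustness
test re-runs the sweeps under a fast-recovery set and asserts only the
inhibitory monotonicity, which is the robust prediction; the excitatory
σ-curve's shape is allowed to move with parameters.

**Input realization.** Each synaptic input is an instantaneous (delta)
current. A delta current's entire effect is its time-integral, so it is
implemented exactly: the membrane jumps by `amplitude` mV (default 8) at
the input's grid-binned arrival time. We first tried a fixed current
confined to a single integration bin and found the delivered waveform —
and hence the inhibition depth — changed materially with the step size;
the jump realization makes the injected drive invariant to `dt` by
construction, and the remaining dt-sensitivity (smooth dynamics between
inputs) is a few percent. The default jump was chosen once, during design,
so that 20 synchronous excitatory inputs always spike the cell, 20
synchronous inhibitory inputs hyperpolarize it deeply, and intermediate
jitter (σ = 10 ms) sustains repetitive firing.

**Inhibition depth** is the pre-input baseline (mean voltage over the
50 ms before the earliest input — robust to initialization transients,
unlike the global resting value) minus the minimum voltage, where the
minimum includes the instantaneous post-jump values; per-iteration depths
are averaged (the alternative — depth of the average trace — can be
recovered from the returned traces). Spike counting covers the full
simulation, `t_end` defaulting to `t0 + 500` ms and always at least
`t0 + 5σ`.

## Problem sizes

The suite runs parameter recovery at 30 neurons per class, 100
permutations, over 20 population seeds; the firing-rate null at 200
simulated neurons; oracle equivalence on 1000 random train pairs; the
model sweeps at 500 iterations per condition; and ANOVA null calibration
at 500 label randomizations over one 40-neuron single-class population
(the factors are the random element under the null, so the expensive
spike-level pipeline need not be re-run per seed). Unit tests use smaller
populations at a 2 kHz protocol rate, which the structural invariants do
not depend on.

## Known limitations

* No NWB ingestion: real recordings must be mapped to `sweep_set` /
  `neuron_record` objects (or the plain-text population format) by the
  user.
* The permutation surrogate imposes no refractory period; for neurons
  whose rate approaches the refractory bound the chance-coincidence level
  is slightly overestimated, making the correction conservative.
* Voltage synthesis is phenomenological (filtered stimulus + AR(1) noise),
  adequate for validating the subthreshold estimator, not for studying
  subthreshold dynamics.
* The downstream model is deliberately non-physiological — one cell, no
  conductances, no network — and supports qualitative statements about
  input timing, not quantitative predictions for any particular circuit.
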