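# spikerel

Spike-timing reliability analysis of frozen-noise current-clamp recordings,
and its consequences for downstream neurons.

## The problem

Cortical neurons answer repeated presentations of the *same* stimulus with
different numbers of spikes at different times. How much of the timing is
reproducible — and whether that reproducibility differs between cell types
such as fast-spiking parvalbumin (PV) interneurons and regular-spiking
excitatory cells — matters for how inhibition and excitation are read out
by downstream targets. `spikerel` is for electrophysiologists and
computational neuroscientists who have (or want to simulate) repeated
intracellular sweeps of a frozen noise current injection and want a
firing-rate-robust, trial-count-robust measure of spike-timing
reliability.

## The statistic

For sweeps *i* and *j* of the same frozen noise at the same intensity, the
directed matching fraction is

    F(i -> j) = (1 / N_i) * #{ spikes t in sweep i : min_k |t - t_k^(j)| <= w }

with coincidence window *w* = 1 ms. A neuron's **raw reliability** is the
mean of F over all ordered sweep pairs; its expectation does not depend on
the number of trials. Because high firing rates produce chance
coincidences, the **corrected reliability** subtracts the same statistic
computed on surrogate sweeps in which each sweep keeps its spike count but
spike times are redrawn uniformly within the stimulus window (default 100
permutations):

    R_corr = R_raw - mean_perm( R_surrogate )

Supporting analyses: nearest-spike latency CDFs, subthreshold (75 %
rheobase) voltage reliability as mean pairwise Spearman correlation,
fast/regular classification from the averaged-spike half-width (fast iff
width < 400 µs), and group statistics (Kruskal–Wallis, pairwise KS, rank
correlations with intrinsic features, species × type two-way ANOVA).

The stimulation protocol is generated exactly as used for in-vitro
cell-type characterization: a 1 s pink-noise template (sum of sines,
1–100 Hz in 1 Hz steps, amplitudes ∝ 1/√f, random phases, CV 0.2 about a
unit DC), replicated ×3 into a 3 s stimulus template and delivered at 75,
100 and 150 % rheobase with 5 s recovery gaps.

A downstream-neuron model — a regular-spiking Izhikevich cell (dv/dt =
0.04v² + 5v + 140 − u + I, du/dt = a(bv − u), cap 30 mV, modified Euler at
0.5 ms) receiving N instantaneous inputs with Gaussian timing jitter σ —
quantifies what input reliability does to a target: synchronous inhibition
hyperpolarizes deeply, jittered inhibition shallowly; synchronous
excitation yields exactly one spike regardless of N, intermediate jitter
unlocks rate coding.

## Worked example

```r
library(spikerel)

# two synthetic classes differing only in spike-timing jitter
classes <- list(
  cell_class("tight", jitter_sd_ms = 0.2, spike_deletion_prob = 0.05,
             extra_spike_rate_hz = 0.5, mean_rate_hz = 15,
             membrane_tau_ms = 8, rheobase_pa = 220),
  cell_class("loose", jitter_sd_ms = 5, spike_deletion_prob = 0.15,
             extra_spike_rate_hz = 1.5, mean_rate_hz = 8,
             membrane_tau_ms = 25, rheobase_pa = 90))
pop <- simulate_population(classes, n_per_class = 30, seed = 42)
tab <- reliability_table(pop, window_ms = 1, n_permutations = 100, seed = 7)
aggregate(corrected ~ class_name, tab, mean)
#>   class_name  corrected
#> 1      loose 0.07454171
#> 2      tight 0.89069421
compare_groups(tab, "class_name")$p_value
#> [1] 2.871949e-11
```

A 0.2 ms-jitter class recovers corrected reliability ≈ 0.89 while a 5 ms
class sits near 0.07 — the correction removes rate-driven coincidences, so
the difference reflects timing alone, and the omnibus rank test separates
the classes decisively.

```r
sweep_sigma(polarity = "inhibitory", sigma_grid = c(0, 10, 50),
            n_iter = 500, seed = 42)
#> <izh_sweep> inhibitory inputs, measure: depth_mv
#>  sigma_ms      mean       sd n_iter
#>         0 160.00000 0.000000    500
#>        10  21.75089 4.219547    500
#>        50  14.23730 2.802360    500
```

Mean inhibition depth falls monotonically as input jitter grows: reliable
(PV-like) inhibition is sharp and strong, unreliable inhibition shallow
and prolonged.

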