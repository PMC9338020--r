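# orgMEA

Spiking and oscillatory network analysis for human brain organoid recordings
on high-density CMOS microelectrode arrays (MEAs).

Organoid slices seated on dense planar arrays (thousands of electrodes over a
3.85 mm × 2.1 mm sensing area) produce two complementary data streams: sorted
single-unit spike trains and low-frequency extracellular voltage (the local
field potential, LFP). `orgMEA` turns those two streams into a network-level
description of the tissue:

- **Firing regularity** — per-unit interspike-interval (ISI) statistics: the
  coefficient of variation CV = σ/µ (1 for Poisson firing, 0 for perfectly
  periodic firing) and classification of ISI distributions as exponential by
  a nonlinear fit of `a·e^(−λx)` to the normalized ISI histogram (R² > 0.9).
- **Population bursts** — 1 ms-binned population firing rates, burst peaks at
  2× the rms rate with ≥ 1 s separation, burst extents at 90% attenuation,
  burst-to-burst similarity (mean |rate difference| over a −100…+350 ms
  window around the peak) and a fractional-change grid
  `(ρ_A − ρ_B)/(ρ_A + ρ_B)` over window choices for condition contrasts.
- **Directed functional connectivity** — pairwise spike time tiling
  coefficients (STTC, Δt = 20 ms), gated by the spike-latency distribution
  (unimodal by Hartigan's dip test at p ≥ 0.1, FWHM ≤ 15 ms), thresholded at
  STTC ≥ 0.35, with direction from the sign of the mean latency. Nodes are
  classed *sender* / *broker* / *receiver* by the normalized degree imbalance
  (threshold 0.8). Null models: within-burst unit-label shuffling (preserves
  the population rate exactly) and degree-preserving double edge swaps.
  Edge-strength distributions are fitted with power-law, exponential,
  truncated-power-law and gamma curves, ranked by AIC.
- **Theta oscillations** — LFP extraction (500 Hz low-pass, 4th-order
  Butterworth, forward–backward, decimation to 1 kHz), zero-phase FIR band
  filters for the classical bands (theta = 4–8 Hz), envelope/phase from the
  analytic signal, pairwise cross-correlation and lag maps against a seed
  electrode (10 µV amplitude floor), burst-anchored signal averages, and the
  circular standard deviation of theta phase around burst peaks.
- **Coherence and phase locking** — imaginary coherence (insensitive to
  zero-lag volume conduction) from Welch cross-spectra (0.5 s windows, 25%
  overlap), k-means detection of coherent electrode pockets, and spike–theta
  phase locking by the Rayleigh test (z = nR², locked at p < 0.05).

A synthetic-data module generates spike trains and LFPs with the statistical
structure this analysis assumes — renewal firing, shared Gaussian burst
envelopes, probabilistic spike transmission along embedded directed edges
(~5 ms latency), burst-modulated theta with spatial phase offsets and 1/f
noise, and von Mises spike–phase coupling — providing ground truth for every
recovery test.

## Worked example

Simulate a 30-unit, 3-minute recording with five embedded directed
connections (60% transmission probability, 5 ± 2 ms latency), then recover
the network:

```r
library(orgMEA)
set.seed(20)
edges <- sample_edges(30, 5, transmission_p = 0.6)
sim   <- simulate_spike_network(n_units = 30, duration_s = 180,
                                edges = edges, seed = 20)
sim$trains
#> spike_train_set: 30 units, 180.0 s, 12426 spikes total

bursts <- detect_bursts(population_rate(sim$trains, "mua_smooth"))
nrow(bursts)
#> [1] 13

g <- build_graph(sim$trains)
g
#> connectivity_graph: 30 nodes, 5 directed edges (density 0.011)
#>   classes: 5 sender / 20 broker / 5 receiver; largest component 2 nodes

head(g$edges[, c("source", "target", "sttc", "mean_latency_ms", "fwhm_ms")])
#>   source target      sttc mean_latency_ms  fwhm_ms
#> 1      2      3 0.5083530        4.454897 5.416667
#> 2      6     27 0.4717770        4.580313 5.247727
#> 3     24      9 0.4603786        4.346561 4.280423
#> 4     11     13 0.4718508        4.466076 5.452273
#> 5     25     28 0.4817975        4.645404 4.635714
```

All five embedded edges are recovered with the correct direction, STTC above
the 0.35 threshold, mean latencies near the injected 5 ms, and narrow
(< 15 ms FWHM) unimodal latency distributions; the sources classify as
senders and the targets as receivers. `run_pipeline()` chains every stage
(curation → ISI → bursts → connectivity → theta → coherence → phase locking)
from a single YAML/R configuration and writes one table per stage;
`compare_conditions()` assembles the control-vs-drug contrasts. A thin
command-line wrapper lives in `scripts/pipeline.R`
(`simulate` / `analyze` / `compare` verbs).

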