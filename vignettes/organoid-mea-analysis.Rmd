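---
title: "Spiking and oscillatory network analysis of organoid MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking and oscillatory network analysis of organoid MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`orgMEA` analyses spontaneous electrical activity recorded from human brain
organoids on high-density microelectrode arrays: spike-sorted single units on
one side, local field potentials (LFPs) on the other, and the statistics that
connect them — firing regularity, population bursts, directed functional
connectivity, theta-band oscillations, imaginary coherence and spike–phase
locking. This vignette describes the models and procedures, the parameters
that matter, the synthetic-data generator used for validation, and the
numerical conventions and limitations a user should know about.

## Data model

Spike times are seconds (`float64`) everywhere inside the package; sample
indices appear only at I/O boundaries (`load_spike_trains` converts a
Kilosort-style text export by dividing by the sample rate). Electrode and
unit positions are micrometres with the origin at the array corner and x
along the long 3.85 mm axis of the sensing area. Voltages are microvolts.
The two containers are `spike_train_set` (per-unit sorted spike times plus
geometry) and `lfp_set` (electrodes × samples matrix with sampling rate and
band label). LFP matrices round-trip through raw little-endian binary
(`int16` with a µV-per-bit gain, or `float32`) with a JSON sidecar describing
the layout.

Automatic unit curation removes units with an ISI-violation fraction
strictly above 0.3, a mean firing rate strictly below 0.05 Hz, or a
waveform signal-to-noise ratio strictly below 5; units exactly at a gate are
retained. The violation fraction is the fraction of ISIs shorter than a
refractory window. Published curation pipelines differ on that window, so it
is an explicit parameter (`refractory_ms`, default 1.5 ms) rather than a
hidden constant.

## Interspike-interval statistics

Units qualify with at least 30 spikes inside a 3-minute selection window.
ISIs are restricted to 8–100 ms before all further statistics — the range
filter comes first, matching the order of the processing chain; whether the
CV should use filtered or raw ISIs is genuinely ambiguous, so
`apply_range_filter` is a switch and the package's limit checks (Poisson
CV → 1, periodic CV → 0) use raw ISIs, where those limits actually hold.
The exponential classification fits `a·e^(−λx)` by Levenberg–Marquardt least
squares (at most 1000 iterations, `ftol = 1e-10`) to the ISI histogram with
bin width = median ISI / 15, bins spanning the data range, counts normalized
to unit sum. R² is `1 − RSS/TSS` over the binned values — the standard
regression definition, since nothing more specific is fixed by the
procedure — and a unit is "exponential" when R² > 0.9. Degenerate samples
(fewer than two nonempty bins) or non-convergence yield a failed fit, never
an error. Condition contrasts use the two-sample Kolmogorov–Smirnov test,
two-sided.

## Population rate and bursts

The population rate is the 1 ms-binned spike count summed over units. Two
smoothing modes exist: a 5 ms moving average (`unit_ma5`, used for
visualisation and burst-relative rate vectors) and the heavier
multi-unit-activity style smoothing (`mua_smooth`: 20 ms sliding mean
followed by a 100 ms Gaussian kernel, truncated at ±4σ, unit area). Burst
*detection* runs on the `mua_smooth` trace: local maxima above 2× the rms of
the trace with at least 1 s separation; each burst extends to where the rate
falls below 10% of its peak (search limited to ±2 s to prevent run-on bursts
in sparse data). The rms is computed over the full recording including
bursts — the simplest reading of a threshold defined in rms multiples — with
an option to iterate the estimate excluding detected bursts. At desk scale
(tens of units rather than a thousand electrodes), detection on the lightly
smoothed 5 ms trace would trigger on two-spike coincidences; the heavy
smoothing is what makes the 2× rms rule meaningful.

Burst similarity takes, per burst, the population-rate vector (5 ms moving
average then a 5 ms Gaussian — the moving average is applied first; the
order is exposed) over −100…+350 ms around the peak, and per burst pair the
mean absolute difference. The condition contrast
`(ρ_A − ρ_B)/(ρ_A + ρ_B)` is evaluated over a grid of windows (starts
−200…0 ms, stops 0…500 ms, step 10 ms) and summarized by the grid mean;
cells with zero denominator are set to 0 with a warning.

## Directed connectivity

The pairwise statistic is the spike time tiling coefficient

STTC = ½ [ (P_A − T_B)/(1 − P_A·T_B) + (P_B − T_A)/(1 − P_B·T_A) ],

where T_X is the fraction of the recording tiled by ±Δt windows around X's
spikes (windows clipped to the recording, overlaps merged) and P_X the
fraction of X's spikes within Δt of the other train; Δt = 20 ms. A term
with a zero denominator contributes 0 (reachable only in degenerate
full-tiling cases). The implementation is validated in the test suite
against a brute-force oracle (explicit interval-union merging, O(n²)
nearest-spike search) to 1e−12.

Edges require three gates besides STTC ≥ 0.35: the latency sample (signed
nearest-spike latencies from a's spikes to b within ±20 ms; the
nearest-neighbour matching rule is one choice among several, and at least 10
matches are required) must be unimodal by Hartigan's dip test at p ≥ 0.1,
and its FWHM — from a 1 ms histogram by linear interpolation at half the
modal bin height — must be at most 15 ms. Direction follows the sign of the
mean latency; bimodal pairs are counted and excluded as putatively
bidirectional. The gates are evaluated for every pair by default
(`gate_order = "gate_first"`), so the bimodal count covers the whole pair
set; `"threshold_first"` computes latencies only above the STTC threshold —
the retained edges are identical either way because the criteria combine by
conjunction. Node classes use the normalized degree imbalance
(D_out − D_in)/(D_out + D_in): strictly above 0.8 is a sender, strictly
below −0.8 a receiver, everything else (including isolated nodes) a broker.
Components are computed ignoring direction.

The dip statistic is implemented with the classic iterative
greatest-convex-minorant / least-concave-majorant construction and verified
against an exact linear-programming formulation of the minimax definition
(frozen oracle values live in the test suite). p-values are Monte-Carlo
against Uniform(0,1) null samples (2000 replicates), with null tables cached
per sample size under deterministic internal seeding so results do not
depend on call order. Inside `build_graph`, where hundreds of distinct
sample sizes occur, the p-value interpolates between null tables on a fixed
size grid with the statistic scaled by √n (the rate at which the null dip
shrinks); `dip_test()` itself defaults to an exact-size table. Latency
samples confined to a single 1 ms histogram bin are treated as trivially
unimodal — at that resolution the dip would only measure floating-point
rounding structure.

Two surrogate families calibrate the thresholds. The burst-shuffle null
permutes unit labels of spikes jointly within each burst, and by default
also within each inter-burst gap: organoid recordings concentrate nearly all
spikes in bursts, but the synthetic recordings used here keep a substantial
baseline between bursts, and leaving those labels fixed would let genuine
pairwise structure leak into the null. Either way the 1 ms population count
vector is preserved exactly. The degree-preserving null rewires the
undirected topology by double edge swaps (10× as many swaps as edges) and
then reassigns each edge's direction uniformly at random — strictly
directed-degree-preserving swaps cannot change sender/receiver classes at
all, which would make the null vacuous for the class statistics it is meant
to test.

Edge-strength histograms (bin 0.05 over 0.35–1) are fitted with four closed
forms — power law `a·x^b`, exponential `a·e^(−cx) + d`, truncated power law
`a·x^b·e^(−cx)` and the gamma curve `(a/(Γ(b)·c^b))·x^(b−1)·e^(−x/c)` — and
ranked by `AIC = n·ln(RSS/n) + 2k`, the least-squares surrogate appropriate
for curves fitted to binned values rather than likelihoods (AICc available
for small samples). A model with more parameters than nonempty bins is
excluded from the ranking, not an error. Condition contrasts report
shared/silenced/induced edge sets (set operations on directed pairs,
fractions relative to the union) and the fractional difference of the two
conditions' gamma fits.

## LFP processing and theta

LFP extraction low-passes the wide-band signal at 500 Hz with a 4th-order
Butterworth filter applied forward–backward (zero phase) and decimates to
1 kHz. Band filters are zero-phase FIR band-passes: windowed-sinc design
with a Hamming window and order 3·fs/low-cutoff (the filter family is fixed,
its order is not; this order gives ~3 cycles of the slowest component, a
common rule of thumb), shortened automatically for traces too short to
support it. Envelope and phase come from the analytic signal (FFT Hilbert
construction); phase is 0 at an oscillation maximum, range (−π, π] — stated
explicitly because polar plots are only comparable under a fixed convention.

The theta correlation map computes, per electrode pair, the maximum signed
Pearson cross-correlation over lags within ±2 theta periods and its lag
(ties broken toward the smallest |lag|). Samples whose theta envelope falls
below the 10 µV noise floor are masked per sample — the floor excludes
amplitudes, and masking whole electrodes would discard usable bursts of
oscillation; electrodes with > 90% masked samples are dropped. The masked
correlation is computed exactly (FFT cross-correlation of the signals, their
squares and their masks) rather than by zero-filling. The seed electrode
maximizes the summed pairwise correlation; the map reports correlation, lag
and equivalent phase offset at the band center against the seed, and the
count of electrodes at or above a 0.2 correlation. Restricting to burst
windows uses the same masking path.

Burst-anchored analyses: event-triggered averages of the theta trace over a
500 ms window (anchors: seed-electrode oscillation peaks with 10 µV minimum
height and 100 ms minimum separation, or population-burst peaks; at least 5
anchors), with an optional ~140 µm square spatial pre-average; the envelope
of the averaged waveform measures phase consistency, and its phase at the
window center gives offset maps. The phase-spread trace is the circular
standard deviation √(−2 ln R̄) of theta phase across bursts at each offset
in −250…+500 ms; electrodes dipping below 1 rad qualify, and their
minimum-spread times and sub-rad windows are reported. Envelope statistics
report the fraction of time the band envelope exceeds k× rms (k = 1, 1.5, 2)
inside versus outside bursts, with the rms optionally taken from a
reference recording (e.g. a pharmacologically silenced noise floor), and
count electrodes with at least a 10% relative burst-over-nonburst increase.

## Imaginary coherence and phase locking

Welch cross-spectra (Hamming windows, 0.5 s, 25% overlap; spectra averaged
over segments before forming coherency) give
`C_xy(f) = S_xy/√(S_xx·S_yy)`; the connectivity value is the absolute
imaginary part averaged over the band's frequency bins. Averaging |Im C|
rather than |mean Im C| is the conservative choice when the sign convention
across bins is not fixed; the signed variant is an option. Zero-lag
coupling — a channel against any scaled copy of itself — scores exactly 0,
which is the property that makes the measure robust to volume conduction.
Regional strength per electrode is the Fisher-Z (atanh) mean of its row,
back-transformed. Pocket detection thresholds the matrix at its 90th
percentile, takes hub electrodes with more than 200 supra-threshold
connections (a figure set by a 1020-electrode array; it is rescaled
proportionally when no electrode qualifies, with a warning), and k-means
clusters the hubs and their neighbours on their binarized connection-profile
rows (k from 2–6 by average silhouette; profiles rather than coordinates,
because the pocket is defined by shared connectivity, not by adjacency). The
tightest cluster's internal coherence is compared against its coherence to
the rest by a Wilcoxon rank-sum test.

Spike phases are read from the phase trace of each unit's nearest electrode
at the nearest sample — at 1 kHz that is ≤ 0.5 ms, about 1° at 6 Hz,
negligible against phase-locking widths, so no interpolation. The Rayleigh
statistic is z = nR² with the standard series approximation for p; units
need at least 30 spikes to be testable, and the locked fraction excludes
untestable units from its denominator by default (a toggle includes them).

## The synthetic generator

The generator produces the structure the analysis assumes, with defaults
chosen once as the study conditions for all validation:

- Each unit is a renewal process with gamma ISIs (shape 1 = Poisson; the
  baseline rate default is 2 Hz, typical of spontaneously active organoid
  units), modulated by a shared burst envelope of Gaussian bumps: 6 bursts
  per minute with ≥ 1 s separation (inter-burst intervals of several
  seconds), 200 ms FWHM (bursts persist for several hundred milliseconds),
  and a peak gain of 4× baseline — prominent, clearly supra-threshold
  bursts of the kind synchronized organoid networks show. Renewal sampling
  uses time rescaling on a 1 ms grid.
- Embedded directed edges inject a follower spike into the target for each
  source spike with the edge's transmission probability (independent
  Bernoulli per spike — the simplest model of probabilistic synaptic
  transmission, no depression), at a latency drawn from a normal
  distribution (default 5 ± 2 ms) truncated above 0.5 ms. Followers do not
  transmit onward by default, keeping ground-truth directionality
  unambiguous; a flag enables chaining. A 2 ms absolute refractory period is
  enforced by deleting the later spike of any closer pair; it is a parameter
  because it subtly biases ISI statistics (at 20 Hz it lowers the Poisson CV
  to ≈ 50/52), and the Poisson-limit checks therefore disable it.
- LFP channels are `(A + D·env(t))·cos(2πft + φ)` plus 1/f noise (spectral
  shaping of white noise, rms-calibrated; 2 µV default, under the 10 µV
  floor): theta at 6 Hz, 20 µV baseline amplitude with 20 µV burst
  modulation, phase advancing by π/2 across the active half of the
  electrodes, the other half noise-only.
- Phase coupling thins a unit's spikes with the von Mises acceptance profile
  `exp(κ(cos(θ − µ) − 1))`; κ = 0 accepts everything exactly.

Every generator takes a mandatory seed, is bit-reproducible, and restores
the caller's RNG state. What the generator does *not* emulate: bursts have
no spatial propagation structure, spike waveforms are never synthesized,
LFP rhythms other than one theta component are absent, transmission has no
short-term plasticity, and edge latencies are stationary. Passing the
recovery tests therefore shows the estimators are correct and calibrated
under the assumed statistical structure — not that real organoid recordings
satisfy that structure.

## Problem sizes and numerical choices

The validation suite runs the connectivity recovery at 50 units × 300 s with
10 embedded edges (p = 0.6, 5 ± 2 ms), null calibrations with 1000 seeded
replicates, and end-to-end determinism on 15-unit/6-electrode runs — sizes
at which every property of interest is already measurable with comfortable
margins. Curve fits cap at 1000 iterations and report failure instead of
throwing. Tie-breaks: cross-correlation lag ties resolve toward the smallest
|lag|; burst peaks are selected greedily by amplitude under the separation
constraint; k-means uses 10 restarts under a fixed seed. Quantities reported
to files are written with fixed formatting so that identical runs are
byte-identical.

## Limitations

Polysynaptic paths are not inferred: an A→B edge can reflect an undetected
intermediate neuron. Bidirectional pairs are excluded rather than split into
two edges. The dip test's grid-interpolated p-values are approximate between
grid sizes (exact at the nominal gate levels used here). Cross-frequency
coupling, gamma phase locking and current-source-density analysis are out of
scope, as are spike sorting itself and any vendor file formats beyond the
text/binary layouts described above.
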