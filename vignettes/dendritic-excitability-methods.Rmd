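---
title: "Methods: dendritic excitability, calcium correction and decoding pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dendritic excitability, calcium correction and decoding pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`l23pipe` bundles the quantitative analyses needed to study how higher-order
thalamocortical input controls the excitability of layer-2/3 pyramidal
neurons in somatosensory cortex: morphological classification of
broad-tufted (BT) versus slender-tufted (ST) neurons, detection of NMDA
spikes and delayed sustained dendritic potentials (DSDPs) in dendritic
voltage recordings, a ratiometric two-channel calcium-trace correction with
permutation-based modulation statistics, and single-neuron decoding of
snout movement. Every stage can be exercised on synthetic data with known
ground truth, so the whole chain is testable without any recordings. This
vignette explains the models, the parameters that matter, and the design
choices where the published procedures leave room.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions used throughout the tests.

**Voltage trials** (`simulate_voltage_trials()`): resting potential (-65 mV)
plus white Gaussian noise (default SD 0.2 mV, typical of a low-noise
dendritic recording after filtering), five 5-ms stimulus pulses at 8 Hz
starting 0.5 s into a 3-s trial, stimulus-locked PSPs as a difference of
exponentials (2-ms rise, 20-ms decay — a standard cortical PSP shape), and
flat-top plateau events with 10-ms sigmoid edges, uniform durations
(default 0.25-0.5 s) and variable onset after the last stimulus. Each trial
draws its PSP amplitude mode once: ordinary (2 mV) or, with probability
`p_nmda`, NMDA-spike-like (10 mV); this produces the bimodal per-trial
amplitude distribution the bimodality analysis expects. The generator does
not model conductances, spikes, up/down-state dynamics (except in
hand-built traces for those tests) or electrode artifacts, so passing tests
show detector correctness under the stated signal model, not robustness to
every in-vivo nuisance.

**Morphologies** (`simulate_morphologies()`): stochastic 2D branching trees
written in SWC convention, with the depth-from-pia on the y axis. The BT
parameter set uses two oblique apical trunks, a three-level wide tuft,
a small basal arbor and superficial somata (mean depth 180 um); the ST set
uses a single vertical trunk, a sparse tuft, a large basal arbor and deeper
somata (280 um). These produce apical/basal length ratios above and below 1
and the superficial span/density separation the clustering relies on. Real
reconstructions have tortuosity, tapering and 3D structure the generator
ignores.

**Calcium recordings** (`simulate_calcium_recording()`): Poisson spikes
(default 0.2 Hz, a typical spontaneous L2/3 rate) convolved with a
GCaMP6s-like kernel (0.2-s rise, 1.8-s decay), a shared slow (below
0.2 Hz) log-normal multiplicative artifact per imaging plane mimicking
axial drift, additive common neuropil signal, and white measurement noise;
the structural channel carries the artifact but no activity. Movement is a
rectified 1/f-shaped 20-Hz trace; coupling enters as a power of the
normalized movement on the firing rate, which keeps rates positive and
monotone in movement.

## Event detection and classification

Detection follows the published recipe exactly: the baseline noise SD is
the SD of the samples below the whole-trace median (events are
depolarizing, so the lower half is event-free); the threshold is 3 of
those SDs above the median; the trace is low-pass filtered over 100 ms and
runs above threshold lasting at least 10 ms become events; a conservative
200-ms duration cut separates short events from DSDPs. Three details are
conventions because the source procedure does not state them:

* *Filter type.* "Low-pass at 100 ms" is implemented as a centered
  moving average of 100-ms width with truncated edge windows — the simplest
  filter with a stated time-domain scale.
* *Amplitude reference.* Event amplitude is measured from the whole-trace
  median, consistent with the noise definition. Mean amplitude during the
  event is the default; peak is available via `amplitude = "peak"`.
* *Post-stimulus window.* Detection starts 50 ms after the last stimulus
  offset so the decaying evoked PSP is not counted as an event, and runs to
  the end of the trial.

A threshold crossing on a smoothed flat-top event moves its apparent edges
outward by up to half the smoothing window on each side; with a 100-ms
window the worst-case duration bias is one window, which is why the
duration-recovery checks use a 100-ms tolerance. At the tested
signal-to-noise ratio (plateau amplitude 5 times the noise SD) the median
duration error is a few milliseconds.

## Bimodality and NMDA-spike strength

The bimodality coefficient is Sarle's statistic
$BC = (S^2 + 1) / (K + 3(N-1)^2/((N-2)(N-3)))$ computed with moment
estimators of skewness $S$ and *excess* kurtosis $K$. The excess
convention is the only reading consistent with the published 0.5
threshold: with raw (non-excess) kurtosis even an ideal two-point mixture
stays at 1/3, so the criterion could never fire. Limits: $BC \to 1/3$ for
a Gaussian, $BC \to 1$ for a 50/50 two-point mixture. When $BC > 0.5$ the
per-trial amplitudes are split by 2-means (deterministically initialized
at the sample extremes); the higher-mean cluster is the NMDA-spike class,
and NMDA-spike strength is the NMDA trial fraction times their mean
amplitude. A degenerate single-cluster outcome yields fraction 0.

The reversal potential of DSDP-suppressing currents is the zero crossing
of an unweighted least-squares line of event amplitude against holding
potential (the fit form is not stated in the source; OLS is the neutral
choice). The potassium Nernst potential uses R = 8.314 J/(mol K),
F = 96485 C/mol and the recording-bath temperature of 36 °C; with 2.5 mM
external and 138 mM pipette K+ the closed form gives -106.8 mV.

## Calcium-trace correction chain

The chain is rescale → ratiometric (axial) correction → neuropil
subtraction → dF/F0, with the published constants: 500-ms exponential
moving average, 180-s centered rolling windows, 8th-percentile window
minima, window medians, r = 0.7, 30th-percentile F0. Decisions where the
published index ranges are ambiguous:

* Rolling windows `(t-90 : t+90)` are read as ±90 *seconds*; at the trace
  edges windows are truncated rather than padded.
* The EMA coefficient is `alpha = 2/(n+1)` with `n` the 500-ms window in
  samples, the standard span convention.
* The neuropil traces run through the identical rescale/correction chain
  (with their own structural reference) before subtraction.
* Samples where the rescaled structural trace is nonpositive are flagged
  in a mask and propagated as NA rather than silently clamped.

On constant input the chain returns exactly zero dF/F0. Because the
rescaling maps the structural channel onto the activity channel's rolling
minimum/median range, an *active* artifact-free trace is rescaled by a
factor close to (window median)/(window 8th percentile); the near-identity
property therefore holds exactly at rest and the artifact-suppression
properties are what matter on active traces. The suppression checks run in
the artifact-dominated regime the property describes (artifact log-SD 0.3,
sparse 0.05-Hz firing, 0.3 a.u. noise): variance reduction above 50% and
an artifact-correlation drop above 2x.

Modulation calling uses Cohen's d with the pooled SD and a permutation
test that shuffles individual datapoints between the before and after
traces (1000 shuffles, add-one two-sided p-value). Datapoint shuffling is
what the published procedure states, despite temporal autocorrelation in
dF/F traces; a contiguous block permutation (5-s blocks) is available but
off by default to match it. A neuron is called modulated when p < 0.01 and
|d| > 0.2, and the modulation index is the relative change
(after - before)/before with an epsilon guard near zero baselines.

## Decoding

Movement is the sum of absolute x/y derivatives, low-passed at 1 Hz with a
zero-phase Butterworth filter. Rates are inferred by simple nonnegative
AR(1) deconvolution (decay 1.8 s) after subtracting a rolling-percentile
baseline; the published saturating-indicator deconvolution is treated as a
pluggable backend, not re-derived. Features are the eleven 50-ms-binned
time shifts from -250 to +250 ms with boundary-value padding at the edges.
The regressor is a random forest (`ranger`) with 128 trees, minimum node
size 2 and `mtry = max(1, floor(p/3))`, evaluated by 5-fold
cross-validation. Folds are *contiguous temporal blocks* (the published
procedure states only 80/20 5-fold): random bin assignment would leak
autocorrelated samples between train and test and inflate prediction
power. PP is the Pearson correlation between observed movement and the
concatenated out-of-fold predictions; per-fold correlations are also
reported. Noise power mean-centers the trace, zeroes all FFT components
outside 0.5-5 Hz, inverse-transforms and sums squared magnitudes; a 10-Hz
trace sits exactly at the Nyquist edge of that band and is accepted.

## Morphology features

Apical and basal dendrites are assigned by whether each stem originates
above (pia side) or below the soma centroid. `span_200` is the maximal
lateral extent of dendrite within 200 um of the pia, and `density_200` is
the cable length in that region divided by the span x 200 um rectangle —
"density" is not formally defined in the source, and this coverage-style
definition makes span and density complementary axes. Lengths are 2D
(slice-plane) segment sums; slice-thickness (z) is ignored because
coronal-slice reconstructions are effectively two-dimensional. A branch is
a path between consecutive topological events (stem origin, bifurcation,
terminal). Clustering is 2-means on z-scored (span, density) with 50
restarts under a fixed seed; the cluster with higher mean density is BT by
definition, so labels never depend on the k-means index; 95% ellipses come
from per-cluster Gaussian fits at the chi-square(2) 0.95 quantile. Overlap
with laminar afferent profiles is the dot product of unit-sum profiles on
shared bins (the source does not state the pre-normalization; unit-sum
makes the score a pure shape overlap in the spirit of Peters' rule), with
linear resampling when bins differ.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at sizes a
single-core laptop handles in minutes: 200-300 voltage trials of 3 s at
10 kHz, 40 synthetic reconstructions, 300-s calcium sessions at 10 Hz,
500 null neuron pairs of 6000 samples with 1000 permutations each
(the permutation kernel is a small C++ routine using R's RNG), and
12000-bin decoding runs. Seeds are explicit arguments everywhere; no
generator touches the global RNG state (`with_seed` restores it), and
fixed seeds give bit-identical outputs, manifests included.

Known limitations: the plateau detector inherits the one-window duration
bias described above; the rescale/correction chain assumes a strictly
positive structural signal; datapoint permutation is anticonservative
under strong autocorrelation (use the block option when that matters); and
the synthetic generators, while matched to the documented signal
structure, are simplifications — passing tests demonstrate algorithmic
correctness under the stated models, not performance on arbitrary real
recordings.
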