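# l23pipe

Analysis pipelines for studying how thalamocortical afferents control the
excitability of layer-2/3 (L2/3) pyramidal neurons in somatosensory cortex.
The package is aimed at cellular neurophysiologists who record from
dendrites in slices or image population activity in vivo and need the
surrounding quantitative machinery to be reproducible and testable:

* **Morphology** — features from SWC reconstructions, 2-means
  classification of broad-tufted (BT) vs slender-tufted (ST) neurons from
  superficial dendritic span and density, and axo-dendritic overlap scores
  (dot products of unit-sum laminar profiles, in the spirit of Peters'
  rule) against POm/VPM/M1/S2 afferent templates.
* **Dendritic electrophysiology** — event detection in voltage trials
  (threshold 3× the SD of the below-median samples, 100-ms low-pass,
  ≥10-ms events), classification of delayed sustained dendritic potentials
  (DSDPs, duration > 200 ms) and their trial statistics; NMDA-spike calling
  via Sarle's bimodality coefficient
  `BC = (S² + 1)/(K + 3(N−1)²/((N−2)(N−3)))` (excess kurtosis, bimodal when
  BC > 0.5) followed by 2-means labelling; reversal-potential fits and the
  potassium Nernst potential.
* **Calcium traces** — the ratiometric two-channel correction chain
  (structural-channel rescaling on 180-s rolling 8th-percentile/median
  statistics, division-based axial correction, neuropil subtraction with
  r = 0.7, dF/F₀ against the 30th percentile) and modulation calls from
  Cohen's d with a 1000-shuffle permutation test (P < 0.01, |d| > 0.2).
* **Decoding** — single-neuron prediction of snout movement from eleven
  time-shifted (±250 ms, 50-ms bins) inferred firing-rate features with a
  random forest (128 trees, min node 2, mtry = max(1, ⌊p/3⌋), 5-fold CV on
  contiguous blocks); prediction power (PP) is the Pearson correlation of
  observed vs predicted movement, with an FFT noise-power (0.5–5 Hz)
  control.
* **Synthetic data** — seeded generators for every input (voltage trials
  with PSPs/NMDA modes/plateaus, BT/ST trees, two-channel calcium with a
  shared multiplicative artifact, laminar profiles, movement traces) with
  complete ground truth, so every stage is testable end to end.

## Worked example

The numbered scripts under `analysis/` form a small end-to-end study over
synthetic data (run them in order from the repository root;
`01_simulate_data.R` writes the shared datasets under `results/data/`).
For instance, the dendritic-event analysis:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/03_dendritic_events.R
```

prints

```
detected 23 events (12 DSDPs) across 30 trials; 12 plateaus injected
DSDP probability 0.40, mean total duration 0.180 s, frequency 0.206 Hz
evoked amplitudes: BC = 0.731 (bimodal: TRUE), NMDA fraction 0.43, strength 3.52 mV
```

Read: all 12 injected plateau events are recovered as DSDPs (40% of trials
contain at least one, matching the generator's 0.6 events/trial with some
trials holding none), and the per-trial evoked-amplitude distribution is
bimodal (BC 0.73 > 0.5), with 43% of trials carrying the high-amplitude
NMDA mode — the generator injected them with probability 0.5. The
morphology script reports 20/20 BT/ST clustering accuracy and higher
POm-overlap for BT neurons; the calcium and decoding scripts report
modulation calls and per-neuron PP against a shifted-alignment control.

Equivalent programmatic entry points: `run_workflow(run_config("ephys"))`,
`"calcium"`, `"morpho"`.

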