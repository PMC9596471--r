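# subnanospec

Computational analysis of **sub-nanopore protein nanospectra** — the
blockade-current time series recorded while a single denatured peptide
translocates through a pore whose waist is about the size of one amino
acid. Because the instantaneous blockade tracks the volume of the residues
occluding the waist, the fluctuation pattern of a nanospectrum is a
sequence fingerprint of the peptide. `subnanospec` provides the full chain
from raw ionic-current traces to a statistically calibrated peptide match:

* **Event extraction** — running-median baseline, k·σ thresholding and
  CUSUM boundary refinement on ABF or TSV traces; blockade descriptors
  ΔI = I₀ − I, Δt, ΔI/I₀ and the binned/smoothed duration–depth heatmap.
* **Preprocessing** — duration filtering (events shorter than 170 µs are
  discarded), resampling of every event to a fixed m = 500 points
  (neighbour averaging when longer, linear interpolation when shorter) and
  z-normalisation.
* **Residue encodings** — the six per-residue feature sets: single
  amino-acid volume (1AAV), volume plus summed neighbour volumes (3AAV),
  four volume-group features (AAG), and their `-P` variants with a 1–5
  terminal-distance position feature.
* **Theoretical nanospectra** — ordinary least squares from features to
  observed per-residue signals; per-residue predictions t̂ᵢ expanded to
  length m by linear interpolation between anchors at the residue dwell
  centres.
* **Slope-constrained DTW** — dynamic time warping with step blocks
  (1,1), (2,3), (3,2), so every matched time-period ratio stays in
  [2/3, 3/2] (6 points on one axis consume 4–9 on the other) and the
  classic singularity pathology cannot occur; squared-error cost,
  O(m²) dynamic program (compiled core), deterministic traceback, and the
  Pearson correlation (PCC) read along the warp path.
* **Consensus building** — orientation calls (forward = N-terminus first)
  by comparing PCC(S, T) with PCC(S′, T); the element-wise **average
  consensus**; and the **progressive-alignment consensus** that folds the
  t = 50 best-aligned spectra into the consensus with weights
  (u + i − 1) : 1, u = 30.
* **Significance** — empirical p-value of the observed path PCC against
  10,000 random decoy peptides of the same length (plain counting
  fraction).
* **Simulator** — synthetic traces and nanospectra with known per-residue
  ground truth (dwell-time jitter, additive noise, random translocation
  orientation), so every stage is testable without instrument data.

## Worked example

Simulate a study of the 42-residue amyloid-β fragment and run the whole
pipeline (the event generator draws log-normal durations with median
170 µs, so roughly half the raw events survive the duration filter):

```r
library(subnanospec)

cfg <- simulation_config(peptide = peptide_ab42(), n_spectra = 300,
                         noise_sd = 0.3, dwell_cv = 0.3, seed = 7)
sim <- simulate_dataset(cfg)
run <- run_pipeline(sim$spectra, peptide_ab42(),
                    pipeline_config(n_decoys = 2000, seed = 8))
run
```

```
[input] 300 nanospectra
[filter] 149 kept (duration >= 170 us)
[orient] 72 forward, 77 backward
[consensus] alignment consensus from 149 spectra
[model] fitted 1AAV-P on 42 residue points
[align] PCC (average) 0.9392, PCC (alignment) 0.9902
[significance] p = 0 over 2000 decoys
nanospectral pipeline run
  peptide: DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA (42 residues)
  spectra: 300 in, 149 after 170 us filter (72 forward / 77 backward)
  PCC vs 1AAV-P model: average 0.9392, alignment 0.9902
  p-value: 0 (2000 decoys, seed 8)
```

Reading the report: 149 of the 300 simulated translocations last at least
170 µs; their orientations split almost evenly, as expected when either
terminus may enter the pore first. The average consensus of the oriented,
resampled spectra correlates at 0.94 with the fitted 1AAV-P theoretical
nanospectrum, the progressive-alignment consensus raises this to 0.99, and
none of the 2,000 random decoy peptides reaches the observed correlation,
so the empirical p-value is 0 (< 1/2000).

`plot(run$consensus, template = theoretical_spectrum(peptide_ab42()))`
overlays the consensus and theoretical nanospectra;
`plot(blockade_heatmap(sim$spectra))` shows the duration–depth density.

A thin command-line front end covers the same stages
(`inst/exec/subnanospec.R extract | simulate | run`).

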