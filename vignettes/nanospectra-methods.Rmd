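---
title: "Methods: sub-nanopore nanospectrum analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sub-nanopore nanospectrum analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnanospec)
```

# The measurement model

When a denatured peptide is driven through a pore whose waist is roughly
the size of a single amino acid, the ionic current drops from the open-pore
level $I_0$ to $I$, and the blockade $\Delta I = I_0 - I$ tracks the volume
of the residues occluding the waist. One translocation yields a
*nanospectrum*: the time series of blockade signals
$S = s_1 s_2 \dots$ over the event duration $\Delta t$. The package's task
is to decide, with a calibrated error rate, whether a collection of
nanospectra matches a candidate peptide sequence.

The working assumptions, which the whole chain inherits, are:

* the expected blockade at each instant is (approximately) linear in
  features of the residue currently in the waist — primarily its volume;
* residues pass in sequence order, forwards or backwards, with variable
  but positive speed (no back-stepping is modelled; a back-stepped
  translocation simply aligns worse);
* amplitude units are uninformative: every spectrum is z-normalised, so
  only the fluctuation *pattern* matters, and the Pearson correlation
  coefficient (PCC) — which is affine-invariant — is the natural match
  score.

# Stage by stage

## Event extraction

`detect_events()` re-implements the standard open-source family of
nanopore event detectors: a running-median baseline (window 501 samples by
default, i.e. ~1 ms at 500 kS/s), a detection threshold of
`threshold_sigma` (default 4) times the robust noise SD (MAD of the
baseline residuals), bridging of sub-threshold gaps up to 5 samples, and a
CUSUM-style change-point refinement of each boundary (the split maximising
the between-segment sum of squares within ±8 samples of the threshold
crossing). Events shorter than 42 µs are discarded at extraction; this
floor is distinct from, and deliberately lower than, the 170 µs analysis
filter, so the stored event set still supports the duration–depth heatmap
across its natural range. No event-detection parameters are reference
values — the defaults are engineering choices validated against the
simulator (≥ 95% sensitivity, boundary error within 2 sample periods at
dip depths ≥ 5 noise SD).

Fractional blockades $\Delta I / I_0$ are clipped to $[0, 1]$ only for the
heatmap; stored signals are never clipped.

## Filtering and resampling

Events shorter than 170 µs are removed (`filter_by_duration()`, boundary
kept: the rule discards *strictly shorter* events). Each surviving event
is resampled to m = 500 points: neighbour averaging when longer — bin $j$
covers input indices $[\mathrm{round}(jL/m), \mathrm{round}((j+1)L/m))$
with round-half-up, which makes bins as equal as possible and reduces to
plain pairwise averaging at even ratios — and linear interpolation at 500
equally spaced positions when shorter. Z-normalisation uses the
*population* SD so the output SD is exactly 1; constant signals are a
hard error rather than a silent NaN.

## Residue encodings

With volumes $b_1 \dots b_n$ (virtual flanks $b_0 = b_{n+1} = 0$), the six
encodings are 1AAV $[b_i]$; 3AAV $[b_i,\; b_{i-1}+b_{i+1}]$; AAG, the
volume placed in one of four group slots (minuscule G,A,S,C; small
T,D,P,N,V; intermediate E,Q,H,L,I,M,K; large R,F,Y,W); and their `-P`
variants with the appended position feature
$x_P = \min(i,\; n-i+1,\; 5)$. The `min` form is used because for
peptides shorter than nine residues the three-branch piecewise definition
overlaps; for $n \ge 9$ (both bundled fixtures have $n = 42$) the two are
identical, and the `min` form is symmetric under reversal for every
length, which the orientation logic relies on.

The bundled volume table is the Zamyatnin residue-volume set (Å³). Which
published volume column the reference analysis used is not recorded;
the table is therefore a plain TSV (`inst/extdata/aa_volumes.tsv`) that
can be swapped via `load_volume_table(path)`. Validation requires all 20
residues, positive volumes, and strictly increasing group *mean* volumes;
it deliberately does not require the groups' volume ranges to be disjoint,
because the published set violates that (valine, 140.0 Å³, exceeds
glutamate, 138.4 Å³, across the small/intermediate boundary). Volumes are
used unscaled: the regression absorbs units, and PCC is affine-invariant,
so the unit choice cannot affect rankings.

## Theoretical nanospectra

`fit_blockade_model()` is ordinary least squares with an intercept. The
intercept is always included: on z-scored targets it is near zero and
harmless, and it keeps the model honest when a feature column is shifted.
Encoding comparison uses two-fold cross-validation with the two peptides
as folds, reporting the MSE *pooled* over both folds' residuals — with
equal fold sizes (42/42) pooling and averaging coincide, and pooling is
the convention recorded here.

`expand_to_spectrum()` places anchor $k$ at output position
$(k - \tfrac12)\, m/n$ — the centre of residue $k$'s equal dwell
segment — interpolates linearly between anchors, and extends flat beyond
the terminal anchors. Anchor-at-centre is chosen because resampling gives
every residue the same expected number of points, so the residue's dwell
segment should be symmetric about its anchor. Predictions are z-normalised
*after* expansion; the order is immaterial for PCC.

## Slope-constrained DTW

The empirical and theoretical spectra (both z-normalised, checked at
tolerance 1e-6) are aligned with a DTW whose step set is the three blocks

* (1,1), pairing $(i, j)$;
* (2,3), pairing $(i-1, j-2), (i, j-1), (i, j)$;
* (3,2), pairing $(i-2, j-1), (i-1, j), (i, j)$;

with squared-error cost, $D[0][0] = 0$ and all other borders unreachable.
This is the minimal step set whose reachable local slopes are exactly
$\{2/3, 1, 3/2\}$, enforcing the stated bound that any 6 points on one
axis are matched against between 4 and 9 points on the other, and making
singularities (long runs frozen on one index) structurally impossible.
The within-block pairing puts the middle point of the longer side with the
later point of the shorter side, so every index is matched and the cost is
additive. Traceback ties prefer (1,1), then (2,3), then (3,2) — output is
deterministic. The dynamic program and traceback are compiled (Rcpp);
correctness is established against an exhaustive enumeration of all
constraint-satisfying block paths at small m, and every traceback is
audited against the 6-point/4–9-point window rule.

The match score is the PCC of the two sequences read along the warp path,
each path pair contributing once (duplicated indices allowed). Whether
the reference analysis correlated path pairs or a warped projection is not
recorded; path pairs are the convention here, and the diagonal path
reduces it to the plain PCC.

## Orientation and consensus

Orientation compares un-warped correlations against the 1AAV theoretical
template: forward iff $PCC(S, T) > PCC(S', T)$, ties called backward (the
literal "otherwise" branch) with an ambiguity flag, since near-palindromic
signals genuinely cannot be oriented. Orientation always uses the 1AAV
template even when scoring later uses 1AAV-P, mirroring the reference
design's split usage.

The average consensus is the element-wise mean of the oriented, resampled,
z-normalised spectra. The progressive consensus ranks all spectra once by
DTW distance to the average consensus (rank-once, not re-ranked after each
update: the ranking is described before the update loop), then folds in
the top t = 50 spectra. Each update aligns the spectrum to the *current*
consensus and projects it onto the consensus axis — for every consensus
index, the mean of the spectrum values the path matches to it — which is
the only way a weighted average is well defined across warps; the update
is $C \leftarrow ((u+i-1)\,C + \mathrm{proj}) / (u+i)$ with u = 30. As
$u \to \infty$ the progressive consensus provably returns the average
consensus, a limit the tests assert at $u = 10^9$.

Per-residue data points are extracted from the consensus–theory alignment
as the mean of consensus values matched to theoretical indices in residue
$k$'s segment $[(k-1)m/n,\; k\,m/n)$, yielding exactly $n$ rows. A
subtlety worth recording: for a noise-free consensus equal to the expanded
theoretical spectrum, the extracted value for residue $k$ is
$v_k + (v_{k-1} - 2v_k + v_{k+1})/8$, not $v_k$ — the segment mean of a
piecewise-linear expansion picks up a curvature term. The identity is
exact for constant and linear anchor profiles, and the extraction is in
any case followed by a regression fit, which absorbs the (small,
pattern-correlated) distortion.

## Significance

Decoys are random peptides of the target's length with residues drawn
i.i.d. uniformly from the 20-letter alphabet; the composition of the
reference decoys is unrecorded, and uniform is the simplest null (recorded
in the output). Each decoy is scored exactly like the target:
predict → expand → z-normalise → constrained DTW → path PCC. The p-value
is the plain counting fraction $\#\{PCC_{decoy} \ge PCC_{obs}\}/n$ — this
matches arithmetic in which a reported p of 0.0002 at 10,000 decoys is 2
decoys — with a $(k+1)/(n+1)$ variant behind `add_one = TRUE` for users
who need $p > 0$. Degenerate decoys (a homopolymer under a position-free
model has a constant theoretical spectrum) score a sentinel PCC of −1,
are counted in the p-value denominator, flagged in the output, and
excluded from decoy mean/SD summaries.

# The simulator: what it emulates and what it does not

`simulate_nanospectrum()` draws, per event: an orientation (backward with
probability 0.5 by default); a duration from a log-normal with median
170 µs and sdlog 1 (spanning tens of microseconds to milliseconds, with
roughly half the events surviving the 170 µs filter — matching the
reference design in which the filter retains about half); per-residue
dwell times with multiplicative log-normal jitter (CV 0.3 by default —
log-normal because dwell times are positive and the jitter should be
scale-free); and i.i.d. Gaussian amplitude noise (SD 0.3 in z-units by
default). The generating waveform is the piecewise-linear interpolant
through the z-scored model predictions anchored at the dwell centres —
the same geometry `expand_to_spectrum()` assumes — and an affine map
places the signal at a 60 ± 10 pA blockade on a 200 pA open-pore current,
sampled at 500 kS/s. Noise and dwell-jitter magnitudes are *not*
reference-reported quantities (the raw deposited data would be needed to
calibrate them); they are moderate values chosen once so that the
property tests are neither trivial nor fragile. An optional heavy-tail
mixture (off by default) emulates slip-stick long-duration outliers. All
randomness flows from one seed with per-spectrum substreams, so any
single spectrum is reproducible in isolation.

Real nanospectra differ in ways the generator does not model: correlated
(non-white) noise, residue-dependent dwell times, hydrophobicity and
mobility effects on the blockade, back-stepping, and baseline drift.
Passing the synthetic tests therefore demonstrates the correctness and
calibration of the *algorithms* under their stated model, not instrument
performance on real data.

One discretisation choice deserves a note. Bin-mean downsampling of a
piecewise-linear waveform reproduces the waveform's grid values exactly
only when the sample count is a multiple of the grid length; across a
kink the bin mean and the centre value differ at the $10^{-5}$ level.
The noise-free identity check (simulate → filter → resample → orient →
consensus → align giving PCC = 1 and DTW distance ≤ 1e-9) therefore fixes
the event duration at 1000 µs — exactly 500 samples at 500 kS/s — so the
resampling step is an exact identity; generic durations are covered by a
separate, appropriately tolerant test.

# Numerical conventions

* Z-normalisation: population SD; zero variance is an error everywhere
  except decoy scoring, where it becomes the −1 sentinel.
* DTW input check: mean within 1e-6 of 0, SD within 1e-6 of 1.
* Resampling bins: round-half-up boundaries (R's `round` is
  round-half-even, which would make bins seed-dependent in edge cases).
* Traceback ties: (1,1) ≻ (2,3) ≻ (3,2); ranking ties: stable input
  order.
* Rank-deficient regression designs are an error naming the collinear
  columns, not a silent pseudo-inverse.
* Orientation ties: backward, with `ambiguous = TRUE`.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at the package's chosen study sizes: DTW oracle equivalence on 200
instances at m ≤ 10 and slope audits on 1,000 pairs at m = 500;
orientation recovery on 500 spectra; consensus-averaging gain over 100
replicates of 100 spectra; null p-value calibration over 200 replicates
of 200 decoys; and two full simulated studies (950 and 4,000 raw events,
10,000 decoys each) in the acceptance script, sized to echo the reference
design's retained counts of roughly 475 and 2,000 nanospectra.

# Known limitations

* The slope-constrained recurrence is the minimal step set satisfying the
  stated ratio bounds; other block-cost conventions satisfying the same
  bounds would give (slightly) different distances, though identical
  module contracts.
* Back-stepping detection, nanospectral clustering of peptide mixtures,
  proteome-scale database search with target–decoy FDR, and
  molecular-dynamics-based prediction are out of scope.
* The ABF reader supports the v1.8 gap-free single-channel float layout —
  sufficient for round-tripping simulated acquisitions and for plain
  single-sweep recordings; multi-channel and ABF2 files are not parsed.
* SVM/random-forest regressors are intentionally absent (they underfit
  the 84-point training regime); the `residue_dataset` interface would
  accommodate them.
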