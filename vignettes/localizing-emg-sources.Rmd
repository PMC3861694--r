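---
title: "Localizing EMG sources on high-density electrode grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing EMG sources on high-density electrode grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgrid)
```

## The model behind the pipeline

Monopolar surface EMG recorded over a muscle shows its largest amplitude on
the skin above the muscle's main innervation zone: the amplitude of a
monopolar montage decays with distance from the source, so the RMS
distribution over a two-dimensional electrode grid has a single, compact
peak per active muscle (or muscle compartment). `emgrid` treats
localization of that peak as a four-stage estimation problem:

1. estimate per-channel amplitude (RMS over a short epoch of a steady
   isometric contraction);
2. partition the amplitude map into basins of attraction of its regional
   maxima (watershed on the rank-equalized map), keeping only the basin
   with the highest raw peak — concurrent low-level activity (crosstalk
   from synergists) forms separate, lower basins and is discarded;
3. summarize the active region by the barycenter of the channels whose
   amplitude exceeds 70% of the basin peak;
4. normalize the barycenter by the subject's forearm anatomy so positions
   are comparable across subjects: `X = x / circumference` (medio-lateral),
   `Y = y / length` (proximal–distal).

The key assumptions are that the contraction is selective enough for a
single dominant source, that the source is stationary over the epoch, and
that a planar grid approximates the (actually curved) forearm surface. The
last assumption is shared by the anatomical normalization itself and is not
corrected for.

## Grid geometry

The packaged standard layout (`standardGrid128()`) is a 12 × 12 lattice at
10 mm pitch with two 4 × 2 blocks removed at the ulnar proximal and distal
corners, leaving 128 electrodes: 12 rows × 8 radial columns plus 8 central
rows × 4 ulnar columns. Column 3 is the anatomical reference column (placed
on the lateral epicondyle–ulnar styloid line), so `x = (col − 3) · 10 mm`
grows toward the radial side and `y = (row − 1) · 10 mm` grows distally.
Grid descriptions are plain JSON (`readGridSpec()`), so other geometries
are expressible without code changes. Where published descriptions of such
grids disagree on which column is "first on the ulnar side", we follow the
12-rows-by-8-plus-8-rows-by-4 reading and keep the reference column index
configurable.

```{r grid}
standardGrid128()
```

## Conditioning choices

**Filter.** Only the pass band (10–400 Hz) is dictated by practice; the
realization is ours: a 4th-order Butterworth applied forward–backward
(`signal::filtfilt`), i.e. zero phase, so filtering cannot shift the
selected epoch relative to the force trace. In-band ripple and stop-band
attenuation of this design are verified against sinusoids in the test
suite.

**Bad channels.** Visual quality assessment is replaced by deterministic
heuristics with configurable thresholds:

* *flat*: variance below 1e−12 × the median channel variance (a dead
  contact);
* *saturated*: more than 1% of samples at the channel's amplitude rails
  (clipping);
* *outlier*: RMS more than 8 robust SDs above the median channel RMS
  **and** more than 3 × the strongest 4-connected neighbour's RMS.

The neighbour condition is what separates a bad contact from the genuine
amplitude peak over an active muscle: a real source elevates an entire
neighbourhood of channels, whereas a failing contact elevates only itself.
A robust-SD rule alone would flag the peak channels of any clean,
high-SNR recording, because the peak-to-median RMS ratio grows without
bound as noise decreases.

**Interpolation.** A flagged channel is replaced sample-wise by the
unweighted mean of its clean 4-connected neighbours — the simplest reading
of "linear interpolation of the neighbouring channels". Flagged channels
are excluded from each other's neighbour sets and each must keep at least
one clean neighbour; cascaded repair is deliberately an error, because the
procedure is designed for the isolated bad contacts typical of grid
recordings (a handful out of 128), not for failed regions.

**Epoch.** The steadiest-force search uses a sliding window stepped one
sample at a time — the exact minimizer, not an approximation — computed
with running sums in O(n); ties go to the earliest window so the choice is
deterministic. Recordings without a force channel use the central window.

## Segmentation choices

**Equalization.** The watershed operates on a rank-equalized map: valid
cells are mapped to `[0, 1]` by rank, ties sharing a value. This transform
is parameter-free, strictly monotone, and invariant under any increasing
rescaling of amplitudes, which makes the segmentation depend only on the
map's topography. A constant map cannot be equalized and degenerates, with
a warning, to a single cluster.

**Watershed.** Flooding the negated map from its regional maxima is
realized as steepest ascent: each valid cell follows its largest strictly
greater neighbour (8-connectivity by default) until it reaches a
regional-maximum plateau; cells draining to the same plateau form one
cluster. Equal-valued plateaus are treated as units, ascent ties are broken
toward the smallest row-major cell index, and masked (missing-block) cells
never take part — so the partition is total over valid cells, unique, and
fully deterministic. On unmasked fixtures the partition agrees with
`EBImage::watershed` up to that implementation's watershed-line cells and
the handful of saddle cells whose basin assignment is
implementation-defined (this is cross-checked in the test suite).

**Threshold.** "Higher than 70% of the maximal value" is read per cluster
and kept strict: a channel at exactly 0.70 × the cluster peak is excluded.
Equal amplitudes `a` all satisfy `a > 0.7a`, so a perfectly flat cluster
returns all its channels. A config switch (`thresholdBase = "global"`)
references the whole-map maximum instead, for sensitivity analyses.
Smoothing is off by default (3 × 3 mean smoothing is available behind
`smooth = TRUE` for very noisy maps).

**Barycenter.** Unweighted mean of the relevant channels' positions;
amplitude weighting is available via `weighting = "amplitude"` but is not
the default, since the thresholded channel set already encodes the
amplitude information and the unweighted mean is the plainer estimator.
Exact peak ties between clusters resolve to the lowest cluster id.

## The synthetic generator

`simulateRecording()` models each source as a band-limited (20–350 Hz),
zero-mean stochastic carrier multiplied by an isotropic 2-D Gaussian
spatial profile, `w(ch) = exp(−d² / 2σ²)`, plus independent white noise per
channel. The expected channel RMS is therefore
`sqrt(Σ w² a² + σ_n²)` exactly, which is all the RMS-map analysis consumes:
second-order statistics are matched, individual motor-unit action
potentials are not modelled. Defaults encode the study conditions the
package is validated under:

| parameter | default | rationale |
|---|---|---|
| sampling rate | 2048 samples/s | standard HD-sEMG amplifier rate |
| spatial spread σ | 15 mm | 70%-threshold footprint ≈ 2.5 cm, consistent with active regions not longer than ~3 cm |
| channel noise RMS | 0.25 × the 20 %MVC source amplitude | power SNR 16 at the peak; recordings have no published SNR, so this is chosen for testability |
| carrier band | 20–350 Hz | inside the 10–400 Hz conditioning band |

`syntheticStudyDesign()` lays out a 10-subject, 7-task study: wrist
extension, radial and ulnar deviation force-tracked at 20/50/80 %MVC (10 s
recordings at 20 and 50, 5 s at 80), plus four untracked 5 s tasks (elbow
flexion, middle/ring/little finger extension) analyzed with central
epochs. Task centres encode the target anatomy — in particular the two ECR
heads share a medio-lateral position but lie 45 mm apart longitudinally
(18% of a 252 mm forearm), and the middle/ring EDC compartments share a
medio-lateral position 22 mm apart longitudinally — so those two pairs
should separate on Y but not on X, while every pair is ≥ 20 mm apart on
some axis. Source amplitude scales with force level, the centre does not;
subject-level offsets (SD 3 mm) are shared across a subject's contractions
and per-contraction jitter (SD 2 mm) is added on top. Ring-finger
extension carries a 0.4-relative-amplitude crosstalk source at the
middle-finger centre to exercise the primary-cluster selection.

What the generator does **not** emulate: volume-conductor anisotropy and
layered tissues, motor-unit recruitment and rate coding, innervation-zone
shifts, force–EMG coupling beyond an independent force trace, non-planar
electrode placement, and correlated (line-interference) noise. Passing the
validation suite therefore demonstrates correctness of the *estimation
chain* under the stated statistical structure, not fidelity to every
physiological detail of real recordings.

## The statistics layer

Subject is treated as a **fixed** effect, matching the factorial design the
analysis mirrors (statistically a random effect would be more natural; the
choice is fidelity, not preference). With one observation per cell the
two-way model has no interaction degrees of freedom, so main effects only
are fitted; in balanced designs all sums-of-squares types coincide, and
the implementation requires balance rather than silently choosing a type.
Pairwise task comparisons use the pooled residual variance of the two-way
fit on each axis, and the 21 pairs on one axis form one Holm–Šidák family
(step-down: the i-th smallest of m p-values is adjusted to
`1 − (1 − p)^(m − i + 1)` with a running maximum; rejection while the
adjusted value stays ≤ α = 0.05). The step-down Šidák procedure is
implemented in the package — `stats::p.adjust` offers Holm's Bonferroni
variant, not the Šidák one — and is tested against a hand-evaluated
oracle and for monotonicity/permutation invariance.

## Validation problem sizes

The test suite validates the chain at the scale the analysis is meant for:
the full 128-electrode grid at 2048 samples/s for localization tests; 100
random source positions at power SNR 10 (plus 20-position sweeps at three
noise levels for the error-monotonicity check) for barycenter recovery,
asserting a median error of at most 5 mm — half the inter-electrode
distance; 1000 simulated null tables for the type-I calibration of the
task factor (acceptance band 0.03–0.07 at α = 0.05); and one complete
synthetic study (130 recordings) for the qualitative pattern that force
*direction* shifts the barycenter while force *level* does not. File-based
pipeline tests use reduced grids and sampling rates, since they exercise
I/O and orchestration rather than the estimator.

## Known limitations

* The grid is planar; medio-lateral positions on a strongly curved forearm
  are compressed near the grid edges, and the normalization by
  circumference inherits this.
* Only the single dominant source is localized; relative activation of
  other clusters (load sharing) is explicitly out of scope.
* Bad-channel detection is heuristic; channels failing in ways that mimic
  plausible EMG (e.g. moderate intermittent noise) are not caught, and the
  manual override list in `localize()` exists for exactly that case.
* Reported ANOVA F statistics from any particular real dataset are not
  reproducible without that dataset; the statistics layer is validated by
  calibration and power simulations instead.
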