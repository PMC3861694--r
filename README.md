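# emgrid

Spatial localization of muscle activity from high-density surface EMG
(HD-sEMG) grid recordings, with a statistics layer for discriminating
contraction tasks.

## The problem

Many forearm muscles — and functional compartments *within* muscles, such as
the two heads of extensor carpi radialis or the finger-specific portions of
extensor digitorum communis — are packed into a few square centimetres of the
dorsal, proximal forearm. A monopolar electrode grid placed over this region
records a two-dimensional EMG amplitude distribution whose single compact
peak sits above the main innervation zone of the active muscle (or
subportion). Localizing that peak, contraction by contraction, makes it
possible to tell apart wrist and finger tasks whose agonists are adjacent or
even parts of the same muscle.

`emgrid` implements the full analysis chain for such recordings, plus a
synthetic multichannel EMG generator with known ground-truth source
positions so every stage can be validated quantitatively.

## The method

For each contraction:

1. **Conditioning.** Monopolar signals (128 channels on a 12 × 12 grid with
   two 4 × 2 ulnar corner blocks missing, 10 mm pitch, 2048 samples/s) are
   band-pass filtered 10–400 Hz with a zero-phase 4th-order Butterworth.
   Bad contacts are detected automatically (flat, saturated, or spatially
   isolated amplitude outliers) and replaced by the mean of their
   4-connected neighbours.
2. **Epoch.** A 3 s analysis window is chosen: for force-tracked
   contractions, the window minimizing the sliding-window force standard
   deviation (the steadiest force); otherwise the central window.
3. **Amplitude map.** The per-channel RMS over the epoch forms the map
   `A(r, c)`.
4. **Segmentation.** The rank-equalized map is partitioned by watershed
   (one cluster per regional maximum); only the cluster with the highest
   raw peak amplitude is kept. Within it, the *relevant channels* are those
   with `A > 0.70 · max(A)` (strict).
5. **Localization.** The barycenter (coordinate mean) of the relevant
   channels estimates the source position; it is normalized by the
   subject's anatomy, `X = x / circumference`, `Y = y / forearm length`,
   so positions are comparable across subjects.

Across contractions, fixed-effects two-way (subject + task) and three-way
(subject + direction + force level) ANOVAs on X and Y, followed by
Holm–Šidák-corrected pairwise comparisons, quantify which pairs of tasks
are separable along which axis.

## Worked example

```r
library(emgrid)

layout <- standardGrid128()
rec <- simulateRecording(
  layout,
  sources   = list(sourceSpec(c(30, 60))),   # ground truth: x = 30, y = 60 mm
  noiseRms  = 0.25,
  durationS = 5, fs = 2048, seed = 42,
  meta = list(subject = "S01", task = "wrist_extension", levelPctMVC = 20,
              forearmLengthMm = 252, forearmCircumferenceMm = 255))
res <- localize(rec)
res
#> LocalizationResult
#>   primary cluster: 4 of 9
#>   relevant channels: 5
#>   barycenter [mm]: (30.00, 60.00)
#>   normalized (X, Y): (0.1176, 0.2381)
```

The noise floor fragments the equalized map into several watershed clusters,
but the highest-peak cluster is the one above the simulated source; the
barycenter of its five supra-threshold channels lands on the ground-truth
position (30, 60) mm, i.e. X = 30/255 ≈ 0.118 of the forearm circumference
and Y = 60/252 ≈ 0.238 of the forearm length.

A whole synthetic study (10 subjects × 7 tasks, wrist tasks force-tracked at
20/50/80 %MVC) runs with:

```r
study <- runStudy(syntheticStudyDesign(seed = 1))
pairwiseDiscrimination(subset(study$table, level_pct_mvc == 20))
```

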