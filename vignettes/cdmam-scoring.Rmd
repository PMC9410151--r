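---
title: "Contrast-detail phantom scoring: model, observer and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-detail phantom scoring: model, observer and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quality control of digital mammography and digital breast tomosynthesis
(DBT) systems is routinely anchored on a contrast-detail phantom of the
CDMAM type: a thin aluminium base carrying gold disks whose diameter
(0.06-2 mm) and thickness (0.03-2 um) vary systematically across a grid,
sandwiched in PMMA so the whole stack is equivalent to about 5 cm of PMMA
or 6 cm of compressed breast. The thinnest gold still detected at each
diameter — the *threshold gold thickness* — traces the contrast-detail
curve of the imaging chain; summary scores and the EUREF limit curves turn
that into pass/fail QC decisions. Commercial phantom readers implement
this scoring as a closed system. `cdmamqc` implements the full scoring
semantics as open, tested code, together with a synthetic-exposure
generator so that every stage can be validated without access to a
physical phantom or the vendor software.

## Phantom model

The grid is a 16 x 16 matrix rotated by -45 degrees with respect to the
detector; rows share a disk diameter, columns share a gold thickness. Only
a staircase band of 207 positions is occupied, and the two extreme corners
of that band — thinnest gold at the largest diameter, thickest gold at
the smallest diameter — carry no disks, leaving 205 scoreable cells. Each
cell holds one disk at its centre and an identical disk in one of its four
corners, drawn uniformly at random from a dedicated, seeded stream so a
phantom's layout is reproducible independently of image noise.

The published description of this phantom family fixes the series
endpoints, the 205-cell count and the two empty corners; the intermediate
series values and the exact occupancy band are phantom-manual details.
`cdmam_phantom()` therefore treats the diameter series, thickness series
and occupancy mask as configuration (with defaults on a near-geometric
16-step ladder; eleven of the diameters, 0.10-1.00 mm, are the standard
reporting columns), and only the counts and corner identities are treated
as invariants. Cell geometry defaults to 7 mm cells, which keeps the
rotated grid inside an 18 x 24 cm field.

## Synthetic exposures

The generator is deliberately a first-order physics emulation: it
reproduces the statistical structure that the scoring pipeline relies on,
not the full imaging chain of any vendor.

* **Contrast.** A disk of thickness $t$ um depresses the local mean by
  $C(t) = 1 - e^{-\mu t}$ with a single effective attenuation coefficient
  `mu_gold` (default 0.15 per um, the order of magnitude of gold
  attenuation at mammographic energies).
* **Counts and noise.** The background expectation is
  `gain * mAs * pitch^2` photons per pixel (default gain 1500 photons per
  mm^2 per mAs), with white Poisson quantum noise plus Gaussian electronic
  noise (default sigma 4 counts), so background variance equals
  `mean + sigma_e^2` and relative noise falls as the square root of dose.
  The clinical tube loads of the emulated dual-resolution DBT unit are the
  defaults: 71/100 mAs (2D, N/H dose), 32/40 (ST) and 50/63 (HR), with
  0.05 mm pixels for 2D/HR and 0.1 mm for ST.
* **Blur.** A Gaussian system PSF of 0.8 pixels is applied to the ideal
  contrast map. Disk edges are rasterised with a one-pixel linear edge
  profile; disks smaller than 1.5 pixels are renormalised so their
  integrated signal matches the true disk area.
* **Tomographic layers.** A reconstructed layer a distance $\Delta h$ from
  the phantom's disk plane receives an additional directional box blur of
  length $k \tan(\theta/2)\,\Delta h$ along the tube-sweep axis
  (first-order tomosynthesis parallax, default $k = 2$); the 40-degree HR
  sweep therefore defocuses faster than the 15-degree ST sweep. All layers
  of a stack share one noise realisation, reflecting that every slice is
  reconstructed from the same projections; this makes in-focus/off-focus
  comparisons paired and guarantees detectability peaks at the disk plane.
* **Synthesized 2D.** `synthesize_s2d()` flattens layers pixel-wise with
  uniform weights, by default over five layers centred one layer off the
  disk plane (a synthesis is anchored on the whole volume, not on the
  phantom's plane). Because the shared noise does not average away while
  the signal is diluted by defocused copies, the s2D image is always worse
  than the in-focus layer — the qualitative behaviour reported for real
  synthesized views. Vendor iterative synthesis is explicitly not
  imitated.

The calibration of `mu_gold` and `gain` was chosen once so that, at the
default noise levels, threshold thicknesses fall mid-series (2D renders
near the EUREF achievable curve, degraded modes above it), which keeps
every psychometric transition observable. What the generator does *not*
emulate: scatter, heel effect, detector glare and lag, anti-scatter grids,
reconstruction artifacts, correlated (reconstruction-shaped) noise, and
real detector MTF/NPS. Passing tests on synthetic data therefore validate
the *scoring semantics*, not the realism of any particular system.

## The automated observer

Scoring one cell is two four-alternative forced-choice (4-AFC) tasks, so
both have a 25% chance level and need no absolute threshold:

1. **Peripheral task** — the matched-filter statistic is evaluated at the
   four cell corners; the chosen corner is the argmax (ties, which have
   measure zero for continuous statistics, resolve deterministically to
   the lowest corner index NE-NW-SE-SW) and is correct when it matches the
   phantom layout.
2. **Central task** — the statistic at the cell centre is compared against
   three disk-free decoy positions on cell-edge midpoints, chosen so that
   no template footprint ever overlaps a real disk.

The statistic itself is a matched filter: a PSF-blurred disk template of
the cell's diameter is centred on the nearest pixel, the background is
estimated from a surrounding annulus, and the template-weighted deficit is
scaled by the standard error of that difference under the annulus noise
estimate — a z-like detectability index that is exactly zero on a
constant image. An alternative fixed-cutoff central rule was considered
and rejected because it would introduce an absolute threshold where the
4-AFC design needs none.

Grid registration is exact when ground truth (or render metadata) is
available; otherwise a translation search around the nominal mount
position maximises the mean probe statistic of the thickest disks, and an
image whose best response stays below a floor is flagged as a
registration failure rather than silently scored.

Two correction rules operate on the scored matrix. The two empty matrix
corners are counted as detected exactly when both of their two in-grid
neighbours are fully detected; this rule is always applied because the
total-detected score is defined over all 207 positions. Nearest-neighbour
smoothing (promote a miss when at least two neighbours are fully detected
and the corner choice was the true corner or edge-adjacent to it) is
available as `scheme = "nn"` because published automated readers use such
a pass, but the default is `"none"`: only the missing-corner rule is part
of the core scoring definition, and the scheme in force is recorded in
every report.

Finally, an *erratic-image guard* computes the pooled correlation between
the per-cell detection outcome and the log detectability index
(thickness x diameter — detectability varies along the grid diagonal, so
thickness alone separates poorly). A well-behaved image detects
high-index disks first (correlation around 0.4-0.7); an image whose
pattern is essentially random — a failure mode automated analysers
occasionally produce on reconstructed layers — scores near zero, falls
below the default floor of 0.25, is excluded from group scores and is
listed in the report.

## Psychometric thresholds

Corner-correct counts are pooled per (diameter, thickness) across the
image set (8-16 images is the conventional set size; per-image scores use
a monotone threshold envelope instead) and fitted per diameter with the
4-AFC psychometric function

$$p(t) = 0.25 + \frac{0.75}{1 + e^{-c(\ln t - \ln t_0)}},$$

by maximum likelihood. The threshold is $t_0$, the thickness at 62.5%
correct — the midpoint of the 25-100% range, the conventional criterion
for 4-AFC tasks. Boundary rules follow the standard scoring convention:
a column already detected at its thinnest sampled gold takes the
column's smallest thickness, one never reaching the criterion takes the
largest. (The published description of this rule says "smallest or the
largest disk *diameter*" where the context implies *thickness*; it is
implemented as thickness.) A failed fit whose empirical rates do cross
the criterion falls back to log-linear interpolation; degenerate columns
return `fit_ok = FALSE` rather than an error.

Automated observers outperform humans, so reported thresholds are mapped
to predicted-human values with a power law `t_pred = r * t_auto^b`. The
default `r = 1.47, b = 1` reproduces the predicted/automatic ratio printed
by the commercial analyser this package mirrors (1.231/0.839 at 0.1 mm);
it is a system-specific calibration, overridable, and — being strictly
increasing — it cannot change any ranking of acquisition modes. The final
smooth contrast-detail curve (`t_fit`) is a least-squares cubic in
log-log space, the smallest polynomial matching the curvature of printed
reference tables; boundary-clipped columns are excluded from the fit when
at least four interior columns remain.

## Image-quality metrics

* `iqf_inv(t, d)` = $100 / \sum_{i=1}^{16} t_{thr,i} d_i$ — larger is
  better; strictly decreasing in every threshold.
* `total_detected()` — cells with both disks detected plus credited
  corners, as a percentage of all 207 positions; it requires a corrected
  matrix so the corner rule cannot be skipped.
* `group_score()` — the default aggregation is the arithmetic mean of
  per-image scores. For the bundled reference set the printed group
  total-detected (68.00) is exactly the mean, but the printed group
  IQF_inv (141.59) is *not* (the mean is 142.17); the analyser's
  aggregation is ambiguous, so a pooled-threshold alternative
  (`score_of_pooled`) is offered and the method used is recorded, with
  neither asserted to be "the" analyser behaviour.
* `euref_classify()` — thresholds at 0.1/0.25/0.5/1.0 mm against the
  EUREF acceptable and achievable limits. The protocol prints limits
  without a boundary rule; the lenient reading (a value exactly at a
  limit satisfies it) is used and documented.
* `tl_index_for_height()` — layer numbering starts at 1 on the
  breast-support surface, so the 22 mm layer of a 1 mm stack is image 23.

Two entries of the bundled reference threshold table (`t_auto = 1.133` at
0.25 mm; `t_pred = 0.585`/`t_fit = 0.590` at 0.80 mm) are apparent
decimal-shift misprints in the source report; they are flagged in the data
and excluded from curve-fit validation, not silently corrected.

## Numerical choices and problem sizes

Randomness is split into three independent streams (corner layout, quantum
noise, electronic noise), each derived from a user seed and logged in the
ground-truth sidecar; renders are bit-reproducible. Matched-filter
templates are cached per diameter and centred on the nearest pixel; the
sub-pixel truncation (at most half a pixel against a PSF of 0.8 pixels)
costs a little statistical efficiency but keeps the observer fast and
symmetric across candidates. The test-suite simulations use the tight
field (grid bounding box plus an 8 mm margin) rather than the full
18 x 24 cm detector, 8-image sets for dose comparisons (the conventional
set size) and shared-noise stacks for focus and synthesis comparisons;
these sizes were chosen as the smallest ensembles at which the orderings
under test are stable by a comfortable margin.

## Known limitations

The observer is *an* automated 4-AFC reader with documented semantics, not
a re-implementation of any commercial analyser's internals; absolute
scores on real images will differ by a system-specific offset even though
rankings and the scoring arithmetic agree. The predicted-human conversion
is a single-ratio calibration, not a validated human-observer model. Real
DICOM ingestion is out of scope in this build: images travel as 16-bit
TIFF with a JSON sidecar carrying the standard exposure header fields
(`KVP`, `ExposureInMilliampereSeconds`, `OrganDose`, `PixelSpacing`, ...),
and `extract_exposure_meta()` reads those fields from any named header
list. Dosimetry is read, never modelled.
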