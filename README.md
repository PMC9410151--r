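# cdmamqc

Automated contrast-detail phantom scoring for digital mammography and
digital breast tomosynthesis (DBT) quality control.

Medical physicists evaluate mammography systems with a CDMAM-type
contrast-detail phantom: a grid of 205 cells, each holding a gold disk at
its centre and one in a randomly chosen corner, with diameters from 2 mm
down to 0.06 mm and gold thicknesses from 0.03 to 2 µm. Reading an image
means, for every cell, picking the corner that holds the peripheral disk —
a four-alternative forced-choice (4-AFC) task with a 25% chance level.
The thinnest detectable gold per diameter traces the contrast-detail
curve; summary scores and the EUREF limits turn it into QC decisions.
`cdmamqc` implements the complete scoring chain as open, tested R code:

* **Phantom model** — the −45°-rotated 16×16 grid, its diameter/thickness
  series, the two disk-free matrix corners, and seeded random corner
  layouts (`cdmam_phantom()`).
* **Synthetic exposures** — 2D, tomographic-layer (TL) and synthesized-2D
  (s2D) renders with thickness-controlled contrast, dose-scaled
  Poisson + Gaussian noise, PSF blur and sweep-angle-dependent defocus
  (`render_phantom()`, `render_tl_stack()`, `synthesize_s2d()`), so the
  whole pipeline is testable without a physical phantom.
* **Automated observer** — a matched-filter 4-AFC reader for both the
  peripheral and the central disk, grid registration, the missing-corner
  and nearest-neighbour correction rules, and an erratic-image guard
  (`score_image()`, `apply_corrections()`, `flag_erratic()`).
* **Psychometric thresholds** — maximum-likelihood fits of
  `p(t) = 0.25 + 0.75 / (1 + exp(−c(ln t − ln t₀)))` per diameter,
  threshold at the 62.5% criterion, boundary rules, predicted-human
  conversion and the smooth contrast-detail curve (`fit_psychometric()`,
  `threshold_table()`).
* **IQ metrics** — the inverse image-quality figure
  `IQF_inv = 100 / Σᵢ t_thr,i · dᵢ` over the 16 diameter columns, the
  total-detected percentage over all 207 grid positions, group scores,
  and EUREF acceptable/achievable classification (`iqf_inv()`,
  `total_detected()`, `euref_classify()`).

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Score a set of four synthetic high-dose standard-resolution tomographic
exposures:

```r
library(cdmamqc)

phantom <- cdmam_phantom(corner_seed = 7)
cfg <- acquisition_config("TL", "ST", "H")

images <- lapply(1:4, function(s) {
  render_phantom(phantom, cfg, seed = s, field = "tight")
})
names(images) <- paste0("exposure", 1:4)

report <- cd_score_set(images, phantom)
report
#> <cd_report>
#>   4 image(s), 0 excluded as erratic
#>   group (mean_of_images): IQF_inv 60.64, total detected 46.01%
#>   EUREF: 1 mm acceptable; 0.5 mm acceptable; 0.25 mm above_acceptable; 0.1 mm above_acceptable

tidy(report)
#> # A tibble: 4 × 5
#>   image_id  iqf_inv total_detected erratic erratic_score
#>   <chr>       <dbl>          <dbl> <lgl>           <dbl>
#> 1 exposure1    59.4           47.3 FALSE           0.541
#> 2 exposure2    63.9           44.0 FALSE           0.568
#> 3 exposure3    60.2           47.8 FALSE           0.568
#> 4 exposure4    59.0           44.9 FALSE           0.535

dplyr::filter(report$thresholds, diameter %in% c(0.1, 0.25, 0.5, 1))
#> # A tibble: 4 × 6
#>   diameter t_auto boundary t_pred  t_fit fit_ok
#>      <dbl>  <dbl> <chr>     <dbl>  <dbl> <lgl>
#> 1     1    0.0500 none     0.0735 0.0670 TRUE
#> 2     0.5  0.0917 none     0.135  0.146  TRUE
#> 3     0.25 0.369  none     0.542  0.415  TRUE
#> 4     0.1  1.42   ceiling  2.09   2.25   TRUE
```

Per image, `iqf_inv` is the inverse image-quality figure (larger is
better) and `total_detected` the percentage of the 207 grid squares with
both disks found. The threshold table gives, per diameter, the automatic
threshold gold thickness (µm), its predicted-human conversion and the
smoothed contrast-detail value; `report$euref` compares the latter with
the EUREF acceptable/achievable limits (this deliberately noisy synthetic
set sits above the acceptable limit at the two smallest reference
diameters). `autoplot(report)` draws the contrast-detail curve against
the EUREF limit curves.

A thin command-line pipeline over the same functions lives in
`inst/cli/cdmam_pipeline.R` (`simulate`, `score`, `report`, `meta`
subcommands). The methods vignette (`vignettes/cdmam-scoring.Rmd`)
documents the model, the observer design and its limitations.

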