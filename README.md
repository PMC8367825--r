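# oromsi

Tools for four-band intraoral multispectral imaging and lesion triage.

Screening for oral potentially malignant lesions (OPML — leukoplakia,
erythroplakia, dysplasia, submucous fibrosis) and squamous cell carcinoma
(SCC) by visual examination is subjective, and locating the most malignant
site of a large lesion for biopsy is hard even for experienced clinicians.
Multispectral diffuse-reflectance imaging offers a quantitative readout:
malignant transformation increases microvascular oxyhemoglobin, deepening
absorption at 545 nm while leaving 610 nm (where deoxyhemoglobin dominates)
nearly untouched, so the pixel-wise image ratio **R610/R545** rises with
disease grade. oromsi implements the computational side of such a device
for researchers working on optical screening: the physics, the scoring, the
classifier, and a fully ground-truthed simulator so the entire pipeline is
testable without clinical data.

## What's inside

- **Reflectance model.** Modified Beer–Lambert over the two hemoglobin
  chromophores, `R(λ) = k(λ)·exp(−d·(ε_HbO2·C_HbO2 + ε_Hb·C_Hb))`, with a
  closed-form two-wavelength inversion returning per-pixel `C_HbO2`,
  `C_Hb`, total hemoglobin `tHb` and oxygen saturation `StO2`
  (`invert_chromophores()`).
- **Phantom simulator.** Scenes with prescribed lesion hotspot ratios and
  oxygenation, inflammation patches, specular saturation and a 405-nm
  fluorescence channel, rendered with per-pixel ground truth
  (`phantom_scene()`, `forward_reflectance()`), plus score cohorts drawn
  from log-normal class distributions calibrated analytically to clinical
  medians/IQRs (`generate_cohort()`).
- **Capture I/O.** TIFF/PNG capture-set directories with a JSON sidecar,
  polygon ROIs with even–odd center rasterization, CSV score tables.
- **Exposure calibration.** The device's retry loop balancing the four
  frame means within a 2.5–4% tolerance band (`calibrate()`).
- **Scoring.** Ratio maps with validity masking, the 5×5 hotspot-mean
  lesion score, healthy-reference means, and an automatic search for an
  inflammation-free reference window (`score_lesion()`,
  `suggest_healthy_roi()`).
- **Classification.** Mean-of-means two-cutoff threshold models per site
  group (all sites, keratinized/non-keratinized, or site-specific), the
  green/yellow/red three-zone readout, and a versioned append-only model
  registry (`fit_model()`, `classify()`, `update_model()`).
- **Diagnostics.** Confusion matrices, sensitivity/specificity/PPV/NPV,
  Mann–Whitney ROC-AUC, quartile class summaries with Tukey-fence outlier
  counts (`evaluate_cohort()`).

Everything tabular flows as tibbles; fitted models support `tidy()` /
`glance()`; ratio maps and models support `autoplot()`. A thin CLI wrapper
with `phantom`, `cohort`, `calibrate`, `process`, `train`, `classify` and
`evaluate` subcommands ships in `inst/cli/oromsi`.

## Worked example

Simulate an OPML-grade lesion, score it, and classify against thresholds
learned from a simulated cohort:

```r
library(oromsi)

scene <- phantom_scene(
  96, 96, seed = 11,
  lesions = list(list(center = c(40, 44), axes = c(18, 14),
                      grade = "OPML", target_ratio = 3.0)),
  specular_spots = list(list(center = c(80, 16), radius = 3))
)
out <- forward_reflectance(scene)

ratio <- compute_ratio_map(out$capture, "R610", "R545")
ratio
#> <ratio_map> R610/R545, 96x96 px, 29 invalid
#>   valid range [1.359, 3.163], mean 1.526

lesion <- roi(rbind(c(18, 26), c(62, 26), c(62, 62), c(18, 62)), "lesion")
score_lesion(ratio, lesion)
#> # A tibble: 1 × 5
#>   ratio_kind hotspot_x hotspot_y score n_window_pixels
#>   <chr>          <dbl>     <dbl> <dbl>           <int>
#> 1 R610/R545         39        33  2.80              25
```

The 29 invalid pixels are the specular spot — saturated, masked, and
excluded from every statistic. The hotspot lands inside the lesion and the
5×5 window mean, 2.80, sits just under the prescribed hotspot ratio of 3.0
because the window straddles the lesion's tapered edge.

```r
cohort <- generate_cohort(c(normal = 200, OPML = 200, SCC = 200), seed = 7)
model <- fit_model(cohort)
model
#> <threshold_model> v1 (all_sites, normals from patient)
#>   cutoffs: normal/suspect 2.28663, suspect/critical 3.41132

classify(score_lesion(ratio, lesion)$score, model)
#> # A tibble: 1 × 3
#>   score class   color
#>   <dbl> <ord>   <chr>
#> 1  2.80 suspect yellow

format_diagnostics(evaluate_cohort(cohort, model,
                                   positive_labels = "OPML")$diagnostics)
#> # A tibble: 1 × 8
#>   sensitivity specificity   ppv   npv   auc cutoff n_pos n_neg
#>         <dbl>       <dbl> <dbl> <dbl> <dbl>  <dbl> <int> <int>
#> 1        88.5          97 0.967 0.894 0.982   2.29   200   200
```

The lesion reads *suspect* (yellow zone): above the normal/suspect cutoff,
below the suspect/critical one — i.e. a potentially malignant lesion that
warrants biopsy guidance rather than immediate alarm. The cohort-level
report gives the sensitivity/specificity of that cutoff for separating
OPML from normal scores in the simulated population.

See `vignettes/oromsi-methods.Rmd` for the model assumptions, parameter
defaults, and the design decisions behind the scoring and calibration
conventions.

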