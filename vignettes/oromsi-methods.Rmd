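---
title: "Methods: multispectral reflectance ratios for oral lesion triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral reflectance ratios for oral lesion triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oromsi)
```

## The measurement model

oromsi works with four co-registered monochrome frames per imaging site:
tissue autofluorescence excited at 405 nm (`F405`) and diffuse reflectance
under narrowband illumination at 545, 575 and 610 nm (`R545`, `R575`,
`R610`). The three reflectance wavelengths are chosen around the optical
behaviour of hemoglobin: 545 nm lies on a strong oxyhemoglobin absorption
band close to an isosbestic point, 575 nm on the second HbO2 band (used as
an inflammation indicator), and 610 nm in a region where HbO2 absorption is
minimal while deoxyhemoglobin (Hb) absorbs roughly 7–8 times more strongly —
making R610 a reference channel that is insensitive to oxygenation.

Diffuse reflectance is modelled with a modified Beer–Lambert law over the
two hemoglobin chromophores:

$$
R(\lambda) = k(\lambda)\,
  \exp\!\big[-d\,(\varepsilon_{\mathrm{HbO_2}}(\lambda)\,C_{\mathrm{HbO_2}}
  + \varepsilon_{\mathrm{Hb}}(\lambda)\,C_{\mathrm{Hb}})\big]
$$

with $\varepsilon$ in cm⁻¹·mM⁻¹, concentrations in mM, a single effective
mean photon path length $d$ (cm) shared by all bands, and $k(\lambda)$ the
dimensionless reflectance of bloodless tissue. A logarithmic form of this
relation without the negative exponent occasionally appears in the applied
literature; absorption must *reduce* reflectance, so oromsi uses the
physically consistent negative-exponent form throughout — forward simulation
and inversion are exact inverses of each other by construction.

Taking two wavelengths gives a 2×2 linear system per pixel,

$$ d\,E\,c = -\ln(R/k), $$

solved in closed form by `invert_chromophores()` using the 545/610 pair.
Totals follow as $tHb = C_{\mathrm{HbO_2}} + C_{\mathrm{Hb}}$ and
$StO_2 = C_{\mathrm{HbO_2}} / tHb$. The package's diagnostic statistic is
the pixel-wise ratio $R_{610}/R_{545}$: as malignant transformation
increases microvascular HbO2, absorption at 545 nm deepens while 610 nm is
barely affected, so the ratio rises monotonically with total hemoglobin at
fixed oxygenation (the exponent is $d\,(g_{545}-g_{610})\,tHb$ with
$g_\lambda$ the StO2-weighted extinction, and $g_{545} > g_{610}$ always
holds for the shipped coefficients).

Absolute mM values are meaningful only relative to the configured $k$ and
$d$; all ratio statistics are independent of a common $k$ scale, which is
why the clinical workflow can skip absolute calibration.

## Default parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| $\varepsilon_{\mathrm{HbO_2}}$ at 545/575/610 | 52 / 60 / 1.3 | cm⁻¹·mM⁻¹ | rounded compiled hemoglobin values |
| $\varepsilon_{\mathrm{Hb}}$ at 545/575/610 | 48 / 34 / 9.8 | cm⁻¹·mM⁻¹ | ditto; Hb/HbO2 at 610 nm = 7.5, inside the physiological 7–8 band |
| $k$ per band | 0.9 | — | bright but unsaturated bloodless baseline |
| $d$ | 0.1 | cm | effective path for superficial mucosa at these wavelengths |
| `min_denominator` | 1/255 | intensity | one 8-bit count; suppresses dark-end division blow-ups |
| scoring window | 5×5 | px | hotspot neighborhood mean |
| StO2 definedness floor | 1e−6 | mM | below this tHb, saturation is reported `NA` |

With these defaults the healthy-mucosa class median ratio of 1.41
corresponds to $tHb \approx 0.068$ mM — a plausible effective blood volume
fraction for superficial mucosa under this factoring of path length.

## The phantom simulator

`phantom_scene()` + `forward_reflectance()` generate captures with known
per-pixel truth. A scene is a homogeneous background (defaulting to the
concentration pair that produces ratio 1.41 at StO2 0.98, i.e. the healthy
class median), elliptical lesions whose hotspot ratio and StO2 are
prescribed and inverted analytically into concentrations
(`target_ratio_to_concentrations()`), inflammation patches that multiply
$C_{\mathrm{Hb}}$, circular specular spots rendered saturated-white and
flagged in the mask, and an F405 channel with autofluorescence loss plus a
protoporphyrin-IX gain inside lesions. Lesion profiles are flat with a
2-pixel raised-cosine edge taper so the hotspot statistic is well defined;
noise is additive Gaussian on normalized intensity, clipped to [0, 1], with
a mandatory seed.

Default lesion StO2 by grade — normal 0.98, OPML 0.85, SCC 0.70 — encodes
the tumor-hypoxia direction. These are simulator conventions for generating
plausible scenes, not clinical claims.

What the phantom does *not* emulate: wavelength-dependent scattering,
melanin and water absorption, speckle, illumination non-uniformity,
inter-band motion, and curved anatomy. Tests passing on phantom data
therefore demonstrate algorithmic correctness (the code computes the model
it claims to), not clinical performance.

### Score cohorts

`generate_cohort()` draws per-class R610/R545 scores from log-normal
distributions calibrated *analytically* to target medians and IQRs: for a
log-normal, $\mathrm{median} = e^\mu$ and
$\mathrm{IQR} = \mathrm{median}\cdot 2\sinh(z\sigma)$ with $z = \Phi^{-1}(0.75)$,
so $\mu = \log(\mathrm{median})$ and
$\sigma = \operatorname{asinh}(\mathrm{IQR}/(2\,\mathrm{median}))/z$.
No fitting is involved; sample statistics converge to the targets as n
grows. Default targets are the observed clinical class summaries (healthy
1.41/0.55, potentially malignant 3.04/0.98, malignant 3.59/1.07).
Log-normality itself is a modelling choice — positive support, right skew
matching the reported outlier behaviour of the malignant class.

Healthy-volunteer normals default to median 1.30 / IQR 0.50, slightly below
patient normals. This encodes field cancerization: carcinogen exposure
shifts even "normal" patient mucosa upward, so volunteer-trained cutoffs
sit lower. The values are a simulator convention chosen once; only the
ordering matters for the properties tested. Anatomical sites are sampled
uniformly over the controlled vocabulary.

## Scoring and classification

`score_lesion()` finds the valid in-ROI pixel with the maximal ratio and
returns the mean of the 5×5 window centred there. Three deliberate choices:

- the window **includes** valid pixels outside the ROI (it surrounds the
  hotspot; restricting to the ROI would bias border hotspots upward);
  border windows are clipped, never padded with invented data;
- saturated/invalid pixels are excluded from both the argmax and the mean;
- ties in the maximum break to the smallest row-major index, making the
  score fully deterministic.

A consequence worth knowing: raising a single in-ROI pixel can *lower* the
score by relocating the hotspot into a poorer neighborhood. The score is
monotone in the current hotspot's value and always bracketed by the window
extremes, and those are the invariants the test suite asserts.

`suggest_healthy_roi()` operationalizes "adjoining region free of
inflammation": among all square windows fully outside the lesion with all
pixels valid, it returns the one minimizing mean R610/R575, via integral
images, with the same row-major tie-break. The pipeline tries 7×7 first,
shrinking to 5×5 then 3×3 when the lesion leaves no room.

Classification uses two mean-of-means cutoffs per site group:
`t_opml` = midpoint of the normal and OPML class means (the
normal/suspect boundary) and `t_scc` = midpoint of the OPML and SCC means.
Only the first boundary is anchored in the published scatter plots; the
second is this package's extension so the three-zone display
(green/yellow/red) is fully specified — its plausibility anchor is the
reported malignant range starting above ≈3.6. Boundary scores go to the
higher-risk class (favor sensitivity). Note that mean-of-means depends only
on class means, never class sizes. Published all-site class means and the
printed cutoff are mutually inconsistent under this rule (the printed
cutoff derives from a different 40-site subset); oromsi implements the
stated rule and does not chase the printed constant.

Site groups: `all_sites`, `keratinized`, `non_keratinized`, or
`site:<region>` (e.g. `site:buccal_mucosa`, pooling left/right). The
keratinized set is gingiva, vermillion border, dorsal tongue, hard palate
and alveolus; everything else is non-keratinized.

The model registry replaces the cloud loop with a local append-only
JSON-lines store plus immutable versioned model snapshots; model JSON is
written with 17 significant digits so replaying the log reproduces every
historical cutoff bit for bit. Network synchronization is deployment, not
method, and is out of scope.

## Exposure calibration

`calibrate()` emulates the device's ambient-light routine. The tolerance on
frame-mean agreement starts strict at 2.5% and relaxes linearly to 4%
across retries (the published procedure only brackets the tolerance by the
retry count; strict-first is the natural reading). Each retry drives the
grand mean toward the 0.5 operating level (mid-range maximizes headroom
against saturation — "optimally exposed" is otherwise unquantified), then
checks agreement; failing that, each band's exposure is scaled by
grand-mean/frame-mean, clipped to [0.1×, 10×] per step. Convergence
requires both the agreement band *and* the operating level: a camera pinned
at full scale balances trivially but is not calibratable, and is reported
as non-converged. For any linear camera the multiplicative update reaches
the fixed point (exposure ∝ 1/gain) in one step, so convergence occurs
within two retries. Frames are balanced against their joint mean, not a
fixed reference reflectance — the published description does not
distinguish the two, and the joint mean needs no extra calibration input.

## Metrics conventions

- Positive call iff score ≥ cutoff, matching the classifier's boundary
  convention.
- ROC-AUC is the Mann–Whitney statistic (ties count half), computed via
  midranks; it equals the trapezoidal area under the empirical ROC and is
  invariant under strictly increasing transforms.
- Quartiles use linear interpolation between order statistics (the
  $p\,(n-1)$ rule, `stats::quantile` type 7); the source material never
  states its convention, so ours is centralized here and in
  `class_summary()`.
- High outliers are counted above the Tukey fence $Q_3 + 1.5\,\mathrm{IQR}$,
  operationalizing "falls above the maximum range".
- Sensitivity/specificity are percentages, predictive values fractions;
  display rounding (2 and 3 decimals respectively) lives only in
  `format_diagnostics()` — raw values are never rounded internally.

## Problem sizes and numerical checks

The test suite exercises: oracle equivalence against scalar-loop
re-implementations (100 random instances each for rasterization, ratio
maps, hotspot scoring, window search, and ROC-AUC); chromophore recovery on
a 128×128 noise-free phantom to 1e−6 mM; hotspot-ratio round trips to
1e−9 for 50 random (ratio, StO2) pairs; cohort calibration at 5000 per
class across three seeds (medians within 5%, IQRs within 10%); and an
end-to-end screening simulation on a 200-site cohort with a held-out half.
These sizes were chosen as the smallest that make the stochastic checks
stable; all are package choices and can be scaled up freely.

Degenerate inputs are handled explicitly rather than by exception where a
sentinel is more honest: noise-driven negative concentrations clip to zero
with a `clip_mask` flag, StO2 is `NA` below the tHb floor, PPV/NPV are `NA`
when no positive/negative call exists, and ratio pixels below the
denominator floor are carried as 0 and excluded from every statistic.

## Known limitations

- Two chromophores only; melanin, water and scattering changes alias into
  apparent hemoglobin.
- One global path length $d$; in tissue, the path differs per wavelength.
- The inversion uses two bands; the 575 nm channel is reserved for the
  inflammation ratio rather than a three-band least-squares fit.
- Thresholds are means-based and unregularized: a single extreme training
  score moves a cutoff (by design — that is the published learning rule).
- The simulator's class distributions are calibrated to summary statistics
  of one clinical cohort, not to raw data, which were never deposited; all
  end-to-end accuracies computed here characterize the simulator, not the
  device.
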