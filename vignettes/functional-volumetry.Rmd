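---
title: "CT functional volumetry and predicted postoperative lung function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT functional volumetry and predicted postoperative lung function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppolung)
```

## The problem

Before an anatomical lung resection (segmentectomy or lobectomy, most often
for early-stage non-small-cell lung cancer), the surgeon needs an estimate of
the patient's *predicted postoperative* FEV1 and DLCO. Classical estimates
assume every bronchopulmonary segment contributes equally — but in patients
with emphysema or other heterogeneous parenchymal damage the segments to be
removed may contribute far less than their anatomical share, and removing
hyperinflated, non-functional tissue can even *improve* postoperative
mechanics (a lung-volume-reduction effect, visible as a postoperative FEV1
above baseline together with a falling residual volume).

`ppolung` implements a density-based alternative: thin-slice CT attenuation
is classified voxel-by-voxel into functional and non-functional tissue, the
planned resection is simulated on a co-registered segment label map, and the
*functional* fraction removed — rather than the segment count — drives the
prediction.

## Tissue classification

Each lung voxel (label map code > 0) is assigned exactly one class from its
attenuation in Hounsfield units:

| class | HU window | interpretation |
|---|---|---|
| `emphysematous` | HU < −900 | destroyed, hyperinflated parenchyma |
| `well_aerated`  | −900 ≤ HU ≤ −501 | functional parenchyma |
| `non_aerated`   | HU > −501 | poorly aerated / dense tissue |

"Functional" means the `well_aerated` class exactly; poorly aerated tissue
counts as non-functional. The window bounds are the conventional
densitometric limits for aerated lung; both are tunable
(`classify_volume(theta_emph=, theta_well_max=)`) with the ordering
`theta_emph < theta_well_max` enforced. The upper boundary is *closed* at
−501 HU: non-integer attenuations in (−501, −500] fall in the non-aerated
class, so the three windows partition the real line with no gap.

Volumes are voxel counts times the voxel volume from the image spacing,
reported in mL (mm³/1000) and rounded only at presentation. Aggregates
(lobe, lung, whole lung) are sums of segment voxel counts — never a
re-classification — so class volumes add up exactly at every level, and
removed + remaining volumes conserve every tissue class exactly in
`simulate_resection()`.

A degenerate plan (no functional tissue anywhere, or an empty removed-volume
denominator) raises an explicit undefined-fraction error rather than
returning a silent 0 or 1.

## Prediction models

Three predictors of postoperative function are implemented:

* **5%-per-segment rule** — `ppo = preop × (1 − 0.05 k)` for `k` segments
  removed, applied flat with no 19-segment renormalisation. `k` may be
  fractional so the rule can be evaluated at cohort means; `k > 20` is
  rejected.
* **Brunelli regressions** — published linear models for the percentage loss:
  FEV1 loss (%) = 21.34 − 0.47·age + 0.49·removed% + 17.91·COPD index, and
  DLCO loss (%) = 35.99 − 0.31·age − 36.47·FEV1/FVC + 0.33·DLCO +
  0.54·removed%, where removed% is the removed *functioning* parenchyma on
  the 0–100 scale. Coefficients default to the published values and are
  overridable only through `brunelli_coefficients()`.
* **Volumetric model** — `ppo = preop × (1 − removed functional fraction)`,
  taking the fraction straight from the CT simulation.

Unit conventions needed care; the package enforces them with explicit
rejections rather than silent rescaling:

* The **COPD index** (Korst) is implemented as FEV1 %predicted (as a
  fraction) + FEV1/FVC — the additive composite that reproduces the
  typical published cohort mean (0.92 + 0.69 = 1.61) exactly. The
  definition is a package decision (the source literature is not always
  explicit) and the index enters only through the overridable FEV1
  coefficient set.
* **DLCO enters its regression in measured units** (mmol/(min·kPa)), not
  %predicted: with %predicted input the formula predicts implausibly large
  losses, while measured-unit input keeps predictions near the preoperative
  value for a typical cohort, which is how published group tables behave.
* **FEV1/FVC enters on the 0–1 scale** (a percent-scale input would
  contribute an absurd −2,500% term and is rejected with a unit hint), and
  removed% on the 0–100 scale (a nonzero value below 1 is rejected as a
  suspected 0–1 fraction).

Predicted losses may be negative (a predicted gain) and are returned
unclamped; only final predicted postoperative values are clamped at zero,
with a warning, when a loss exceeds 100%.

## Cohort analysis

`split_by_response()` partitions a cohort into patients whose measured
postoperative FEV1 (L) strictly exceeds baseline ("increase") and the rest.
Ties go to the decrease group — "showed an increase" read strictly — and the
rule is configurable (`ties = "increase"`). Group summaries are means with
sample SDs (n − 1); groups are compared with the *pooled-variance* unpaired
Student t-test (df = n₁ + n₂ − 2, two-sided p), not Welch, matching the
convention of small surgical series. Zero pooled variance is handled
explicitly: equal means give t = 0, p = 1; unequal means give an infinite t
and p = 0 with a warning. No multiple-testing correction is applied across
variables. `model_deviation()` reports measured − predicted group means,
with FEV1 deviations conventionally printed in mL rounded to the nearest
10 mL (`report = "ml10"`); stored values are never rounded.
`fit_pre_post_line()` is ordinary least squares of postoperative on
preoperative values with per-patient residuals from the line of no change.

## The synthetic generators

No patient-level data ship with the package; every pipeline stage is instead
testable on synthetic objects whose ground truth is known.

**Phantoms** (`make_phantom()`): an axis-aligned partition of the grid into
the ten right-lung segments (S1–S3 upper lobe, stacked slabs along z) and a
single left-lung bulk region used only as a whole-lung denominator, inside a
background margin. Each lung voxel draws its class from per-segment mixture
weights and its HU from that class's normal component — well-aerated
N(−750, 40), emphysematous N(−950, 20), non-aerated N(−200, 50) — truncated
to the class window so the drawn class is the classified class (untruncated,
roughly 10⁻⁴ of well-aerated draws would leak below −900 HU and break exact
round-tripping). The emitted ground truth is the *realized* voxel count per
class, not the target weights, so classification recovers it exactly;
against the target weights the recovered fractions are multinomial, within
1% absolute at 10⁵ voxels per region. Default mixture `(0.80, 0.08, 0.12)`
emulates a mostly healthy smoker's lung with mild emphysema. Phantoms make
no attempt at realistic CT texture, airways, vessels or respiratory phase —
a green phantom test establishes counting/aggregation correctness, not
segmentation performance on real HRCT.

**Cohorts** (`make_cohort()`): marginals emulate a right-upper-lobe
resection series — age 68 (10) years truncated to [40, 90], preop FEV1
2.48 (0.59) L (> 0.8), FEV1/FVC 0.69 (0.09) in (0.3, 0.95), DLCO
6.27 (1.99) mmol/(min·kPa) (> 1), RV 118 (25) %predicted, BMI 27 (4.9),
and 3/2/1 segments resected with probabilities 0.70/0.10/0.20. Marginals
are drawn *independently*; no FEV1–DLCO or age–function correlation is
imposed, because no joint distribution is available to emulate — cohort
tests therefore validate marginal behaviour only.

The outcome model is a minimal single-parameter stand-in for the
lung-volume-reduction mechanism, a testing device rather than a
physiological claim. With `nf` the resected region's non-functional fraction
(Beta(2, 9.11), mean 0.18), `H` the whole-lung healthy fraction
(N(0.83, 0.12) truncated), and each resected segment occupying 6.88% of
total lung volume (so the expected resection at the default segment mix is
17.2% of the lung), the removed functional fraction is
`rff = k·0.0688·(1 − nf)/H` and

```
FEV1_post = FEV1_pre · (1 − rff) · (1 + γ · nf · RV%/100) + N(0, σ).
```

Defaults γ = 0.68 and σ = 0.15 L were fixed once by moment matching: at the
marginal means the multiplicative gain term makes the mean
postoperative/preoperative ratio ≈ 0.95 (a 5% mean loss), and σ puts the
spread of FEV1 change near 9% of the preoperative mean (the realized change
SD lands somewhat above that because the mechanism's own variability adds to
σ; no retuning was done). Setting γ = σ = 0 switches the mechanism off, and
postoperative FEV1 then equals the volumetric prediction exactly — the
parameter-recovery tests exploit this. Postoperative RV falls
proportionally to the resected non-functional volume
(`RV_post = RV_pre · (1 − k·0.0688·(0.4 + 1.5 nf))`), and DLCO declines at
half the removed functional fraction plus noise, keeping diffusion roughly
stable as such cohorts show. All draws flow from one seeded generator per
invocation; the caller's RNG state is saved and restored, and identical
spec + seed gives byte-identical output.

Under these defaults the FEV1-increase group's removed tissue is
systematically less healthy than the decrease group's (higher `nf` both
raises the compensation gain and lowers `rff`), so the directional
group-contrast property holds in essentially all seeded replicates at
n = 20, echoing qualitatively the clinical observation that responders had
resections dominated by non-functional tissue.

## Numerical and I/O choices

* Threshold boundaries are closed as stated above; classification is a
  strict partition of the lung mask on every input.
* Volumes are carried as voxel counts as long as possible; fractions are
  formed once, from sums, so conservation is exact to voxel-count
  arithmetic.
* NIfTI-1 I/O is a deliberately minimal reader/writer (single 3D volume,
  uint8/int16/int32/float32/float64, both byte orders on read, `.nii` and
  `.nii.gz`): no R NIfTI package is assumed to be installed, and the package
  needs nothing beyond spacing, origin and the voxel block. Label tables
  travel as JSON sidecars; cohorts and volumetrics as CSV; pipeline
  configuration as YAML.
* `run_pipeline()` echoes every effective parameter (thresholds,
  coefficients, seed, package version) into the report's provenance block
  and the run log; given a seed, CSV/JSON payloads are byte-identical across
  runs. The CLI (`exec/ppolung`) exits 0 on success, 2 on validation
  failure, 3 on computation failure.

## Known limitations

* No segmentation: real HRCT must arrive with a co-registered anatomical
  segment label map; the package never infers lobes or laterality from
  geometry (the label table is authoritative).
* %predicted values are pass-through inputs; no reference equations are
  computed.
* Only HU thresholding is implemented as the functional surrogate — no
  perfusion, texture or ventilation modelling.
* Cohort-level published statistics that depend on unpublished patient-level
  data (e.g. exact group p-values) are out of reach by construction; the
  tests assert the reproducible worked examples and distributional
  properties instead.
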