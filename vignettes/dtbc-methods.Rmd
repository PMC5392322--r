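---
title: "Digital tumor bud counting and its clinical layer: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital tumor bud counting and its clinical layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtbc)
```

## The measurement problem

Tumor budding — isolated islands of up to about five tumor cells detached
from the main tumor mass — is a histological marker of dissociative growth
and an adverse prognostic sign in several carcinomas, including oral
squamous cell carcinoma (OSCC). Manual bud counting is slow and has poor
inter-observer reproducibility, which has kept it out of routine pathology
reporting. This package implements a digital alternative: on a cytokeratin
(AE1/AE3) immunostained section, every connected DAB-positive island inside
a manually drawn tumor region is labeled, its area measured in square
micrometers, and the **digital tumor bud count (DTBC)** is the number of
islands whose area falls between an artifact floor and a bud-size ceiling.

The package has two layers:

1. an image layer (`read_image`, `load_roi`, `build_mask`, `segment_dab`,
   `label_regions`, `filter_artifacts`, `classify_buds`, `compute_dtbc`,
   `sweep_bud_definitions`), and
2. a clinical layer that treats the DTBC as a biomarker: a logistic risk
   model for occult nodal metastases with cross-validated discrimination
   and calibration (`fit_logistic`, `forward_select`, `roc_auc`,
   `cross_validated_auc`, `hosmer_lemeshow`, `calibration_curve`),
   decision-curve analysis of neck-dissection strategies (`net_benefit`,
   `net_reduction`, `decision_curve`), and tertile-based survival analysis
   (`assign_tertiles`, `kaplan_meier`, `logrank`, `cox_fit`,
   `cox_forward`, `budsize_prognosis_sweep`).

Both layers are exercised end to end on generated data: image phantoms
with exact island-area ground truth (`generate_phantom`) and synthetic
cohorts with known logistic and proportional-hazards structure
(`simulate_cohort`, `cohort_with_target_auc`).

## The counting model

All area arithmetic is physical. A `calibrated_image` carries a
`microns_per_pixel` value, taken from an explicit argument, from TIFF
resolution tags, or from PNG pHYs metadata — in that order of precedence;
with no calibration the read fails, because the two thresholds below are
meaningless in pixels. Scanner metadata conventions vary enough that we
treat an explicit argument as authoritative.

The classifier has three parameters (`bud_params`):

| parameter | default | unit | meaning |
|---|---|---|---|
| `cell_area_um2` | 190 | um^2 | average cross-section area of one OSCC cell |
| `n_cells` | 5 | cells | maximum cells in a bud |
| `artifact_min_um2` | 150 | um^2 | areas strictly below are staining debris |

The bud ceiling is derived, `n_cells x cell_area_um2 = 950` um^2 by
default. A labeled island is a **bud** when
`artifact_min_um2 <= area < bud_max_um2`. Both comparisons follow the
convention of the worked example this implementation reproduces: a region
of exactly 150 um^2 survives the artifact filter, and a region of exactly
950 um^2 is *not* a bud. Whether the original vendor implementation used
`<=` at the ceiling cannot be determined, so the strict rule is the
default and an `inclusive` variant is exposed via `bud_rule`.

```{r}
classify_buds(labeled_regions_from_areas(c(100, 890, 885, 1297)))
```

Connected components are computed under **8-connectivity** (a compiled
two-pass union-find). Diagonal-only contact therefore joins pixels; this
matches the behaviour of common commercial labeling tools and avoids
splitting a single cell whose rasterization touches corner to corner. No
hole-filling or morphological cleanup is applied beyond the two area
filters.

## Stain segmentation

The DAB (brown) signal is isolated by standard optical-density color
deconvolution. Intensities are transformed per channel by
`OD = -log10((I + 1)/255)`; the `+1` avoids an infinite density at zero
intensity and biases OD by under 0.002 at full transmission, negligible
against the default threshold. Concentrations are obtained by inverting
the 3x3 unit-norm H-DAB stain matrix (the widely used published
hematoxylin/DAB vectors, with a residual channel completing the basis);
slides stained differently can override the matrix in `stain_params`.

Two parameters matter:

* `dab_od_threshold` (default **0.15** OD): a pixel is stained when its
  DAB concentration reaches this value. The semi-automated workflow this
  replaces tuned a visual contrast threshold per protocol; an explicit,
  recorded OD threshold is the reproducible stand-in, and 0.15 is a common
  practical default for clean DAB chromogen. There is deliberately no
  automatic threshold selection.
* `analysis_scale_factor` (default **4**): block-mean down-sampling from
  scan to analysis resolution, e.g. a 20x scan analyzed at 5x. Region
  areas are computed *at analysis resolution*, i.e. after down-sampling,
  with the calibration scaled accordingly. Block averaging is exact and
  deterministic, and keeps total stained area stable (within rasterization
  tolerance) across factors.

## The phantom generator

`generate_phantom` renders islands with *exact* pixel areas: an island of
target area `A` at `m` um/px is the `round(A/m^2)` grid cells closest to a
center under a disc, ellipse, or star-shaped blob metric, so the achieved
area is known to the pixel and the set is always connected. Islands are
placed by rejection sampling with at least two pixels of separation, so
8-connected labeling can never merge two islands and the ground-truth
count is exact. Rendering follows the same Beer–Lambert model the
segmenter inverts: `I_c = 255 * 10^(-conc * OD_c)`, optionally over a
hematoxylin-tinted background and with additive Gaussian noise.

What the phantoms do **not** emulate: real chromogen texture, uneven
stain uptake, out-of-focus blur, touching buds, nuclear counterstain
inside islands, and section artifacts like folds. Passing the phantom
tests therefore demonstrates that the counting pipeline is exact for
well-separated stained objects of known size — not that the default OD
threshold is optimal for any particular scanner or staining protocol,
which remains a per-laboratory calibration.

## The cohort generator

`simulate_cohort` emulates an early-stage (cT1–T2 N0) OSCC cohort.
Category frequencies follow typical published distributions for this
population (47% floor of mouth, 42% tongue; 26/59/15% well/moderate/poor
differentiation; 60% non-cohesive front; 29% perineural invasion; 57%
male; 78% heavy smokers; age ~ N(64, 13); depth lognormal with median
4 mm). The DTBC is negative-binomial (mean 400, dispersion 0.9), matching
the strongly right-skewed counts seen per section, where most patients
fall between 0 and 1000 buds. Nodal status is Bernoulli with a logistic
linear predictor; the default intercept (−3.16) was calibrated once, by
Monte Carlo against the default effect sizes, so that the marginal
node-positive fraction is ≈ 0.34, the occult-metastasis rate typical of
this population. Survival uses exponential proportional-hazards models
(OS baseline 0.025/yr with hazard ratios ≈ 1.6 per DTBC tertile, 1.7 for
nodal disease, 1.4 per age decade; PFS baseline 0.012/yr) under a uniform
0–8-year administrative censoring window, giving event fractions near 30%
(OS) and 20% (PFS). These are *generator defaults*, not estimates: their
role is to give the statistical layer a truth to recover.

`cohort_with_target_auc` uses the binormal identity
`AUC = Phi(delta / sqrt(2))`: controls score N(0,1), cases N(delta,1) with
`delta = sqrt(2) * qnorm(AUC)`, so the Bayes-optimal AUC of the composite
score is exactly the target and the implied logistic slope on the score
is `delta`. This provides a generative truth for validating
`cross_validated_auc`.

All generator randomness flows through a single per-spec seed; the
caller's RNG state is saved and restored, so no global state leaks.

## Statistical layer: choices that were genuinely open

* **Model specification.** The candidate set for the nodal risk model is
  configuration-driven (defaults: DTBC tertile, depth > 4 mm,
  non-cohesive front, perineural invasion, cT2, age), with forward
  selection by likelihood-ratio p-value at entry 0.05. Forward selection
  is *re-run inside every cross-validation fold*, so the cross-validated
  AUC pays for model selection; the pooled out-of-fold predictions form a
  single ROC rather than averaging per-fold AUCs, which is more stable at
  a few hundred patients with 10 folds.
* **AUC inference.** DeLong's nonparametric variance (via pROC) for the
  confidence interval, with ties counted one half in the point estimate.
* **Calibration.** Hosmer–Lemeshow with `g = 10` quantile bins and
  `g - 2` degrees of freedom, the reference distribution appropriate for
  *fitted* probabilities from a correctly specified model; tied
  predictions merge bins with a warning and reduce the df.
* **Decision curves.** Standard net-benefit definition
  `TP/n - FP/n * pt/(1-pt)` with an inclusive treatment rule
  (`prob >= pt`), and net reduction vs treat-all
  `(NB_model - NB_all)(1-pt)/pt * 100`; the default grid 1–50% covers the
  clinically debated thresholds for elective neck dissection.
* **Stepwise Cox.** "Conditional forward elimination" is realized as
  forward entry (LR p < 0.05) followed, after each entry, by conditional
  LR removal of any included variable whose p exceeds 0.10, iterated to a
  fixed point with ties broken by candidate order. This is a documented,
  testable approximation of the stepwise mode of legacy statistical
  packages, whose exact internals are not reproduced. Tied event times
  use Efron's approximation by default (more accurate); Breslow is a flag
  for compatibility with software whose default it is.
* **Tertiles.** Cut at interpolated terciles, lower boundary inclusive
  upward, ties share a group — so an excess of identical counts collapses
  groups rather than splitting ties arbitrarily. The bud-size sweep
  (`budsize_prognosis_sweep`) uses the tertile as an *ordinal* covariate,
  reporting a hazard ratio per tertile increment, and summarizes the
  bud-size/prognosis relationship by a least-squares line of log HR on
  the cell-count definition. Cumulative size thresholds (areas up to
  `n x 190` um^2) are used across the sweep; definitions whose counts
  cannot form tertiles (e.g. mostly zeros at one cell) are flagged and
  skipped.

## Numerical and degenerate-input conventions

* Polygon rasterization is pixel-center, even-odd, with a half-open
  boundary rule (a point on a left/bottom edge is inside, right/top
  outside): deterministic, and adjacent polygons tile without
  double-covered pixels. An ROI that misses the image yields an empty
  mask with a warning and a DTBC of 0, not an error.
* An analysis block at the ROI edge belongs to the down-sampled mask when
  at least half its source pixels are inside.
* Logistic fits stop at a relative deviance change of 1e-10 or 100
  iterations; complete separation and singular designs are reported as
  errors naming the offending variables rather than returned as huge
  coefficients.
* `hosmer_lemeshow` drops zero-variance bins from the statistic and
  reduces the degrees of freedom accordingly.
* A zero-length censoring window censors every patient at time zero; a
  single-class outcome, a constant covariate, or a one-group log-rank are
  validation errors, not NaNs.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they
measure. Sizes were chosen so each recovery check has comfortable Monte
Carlo margin while the whole suite runs in about a minute: logistic
recovery at n = 50,000 (coefficients within ±0.05), Cox hazard-ratio
recovery at n = 10,000 (HR 2.0 within ±0.1), cross-validated AUC at
n = 5,000 against a generative 0.83 (within ±0.03), type-I calibration of
Hosmer–Lemeshow and log-rank over 1,000 null replicates (rejection within
[0.03, 0.07] at α = 0.05), and exact oracle agreement of the counting
pipeline over 100 random phantoms.

## Known limitations

* The OD threshold replaces a visually tuned vendor contrast threshold;
  equivalence with any particular commercial segmentation cannot be
  established and per-protocol calibration is expected.
* Whole-slide pyramid formats (NDPI/SVS/CZI) are out of scope; inputs are
  flat TIFF/PNG tiles with a known calibration.
* Buds are counted over the whole tumor ROI; no invasive-front
  localization or intratumoral/peripheral distinction is attempted.
* The survival generator is exponential-PH with administrative censoring —
  adequate for recovery testing, not a model of real follow-up patterns.
* Decision-curve confidence bands (bootstrap) are not implemented.
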