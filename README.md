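# dtbc — digital tumor bud counting and nodal risk modelling for early OSCC

Tumor budding — small islands of up to about five tumor cells detached
from the invasive tumor mass — predicts occult lymph-node metastases and
poor survival in early oral squamous cell carcinoma (OSCC), but manual bud
counting is slow and observer-dependent. `dtbc` implements a fully
deterministic digital score and the clinical analyses built on it, for
pathologists and biostatisticians working with cytokeratin (AE1/AE3)
immunostained sections.

## What it computes

**Digital Tumor Bud Count (DTBC).** On a calibrated RGB section image with
a manually drawn tumor region of interest (GeoJSON polygons; exclusions
for necrosis and salivary glands), the DAB (brown) signal is isolated by
optical-density color deconvolution,

    OD_c = -log10((I_c + 1)/255),    conc = OD · M⁻¹   (H-DAB stain matrix M),

thresholded (default 0.15 OD) at analysis resolution (default 4× block
down-sampling, i.e. a 20× scan analyzed at 5×), and connected stained
islands are labeled under 8-connectivity. With per-cell area
a = 190 µm² and bud size n = 5 cells,

    DTBC = #{ islands : 150 µm² ≤ area < n·a = 950 µm² },

areas under 150 µm² being discarded as staining artifacts. A sweep
re-counts under definitions of 1–20 cells.

**Clinical layer.** Treating the DTBC as a biomarker: a logistic model for
occult nodal metastases with forward likelihood-ratio selection, apparent
and 10-fold cross-validated AUC (DeLong intervals, selection re-run per
fold), Hosmer–Lemeshow calibration; decision-curve analysis (net benefit
`TP/n − FP/n · pt/(1−pt)` and net reduction in unnecessary neck
dissections vs treating everyone); and tertile-based survival analysis —
Kaplan–Meier with at-risk tables, log-rank, univariate Cox and stepwise
multivariate Cox (Efron ties), plus the bud-size-versus-prognosis sweep.

**Generators.** Stained-island phantoms with exact area ground truth and
synthetic cohorts with known logistic/proportional-hazards structure make
every stage testable without patient data (`generate_phantom`,
`simulate_cohort`, `cohort_with_target_auc`).

## Worked example

Score a phantom whose ground truth is known by construction, then run the
clinical layer on a simulated 222-patient cohort:

```r
library(dtbc)

ph <- generate_phantom(phantom_spec(canvas = c(300, 300),
  island_areas_um2 = c(rep(400, 6), 890, 885, 1297, 2000),
  artifact_areas_um2 = c(60, 90), seed = 11))
compute_dtbc(ph$image, ph$rois, stain_params(analysis_scale_factor = 1L))
#> <bud_count_result> DTBC = 8 of 10 regions (artifact floor 150 um^2,
#>                    bud ceiling 950 um^2, strict)
```

The two 60/90 µm² artifacts were dropped, the 1297 and 2000 µm² islands
were labeled but are too large to be buds, and the six 400 µm² islands
plus the 890/885 µm² pair are counted: DTBC = 8.

```r
co <- simulate_cohort(cohort_spec(seed = 1))   # 222 synthetic patients
vars <- c("dtbc_tertile", "depth_gt4", "front_noncohesive", "pni",
          "ct2", "age_c")
m <- forward_select(co, vars)                  # LR entry at p < 0.05
m
#> <risk_model> outcome node_binary, n = 222, logLik = -128.36
#>  (Intercept) dtbc_tertile        age_c
#>      -2.5005       0.8655       0.2451
roc_auc(co$node_binary, predict(m))
#> <roc_result> AUC = 0.701 (95% CI 0.627-0.775, DeLong; 74+/148-)
cross_validated_auc(co, vars, seed = 1, select = TRUE)
#> <roc_result> AUC = 0.653 (95% CI 0.573-0.732, DeLong; 74+/148-)

cox_fit(co, "dtbc_tertile")$terms
#>           term       hr  ci_low  ci_high         p
#> 1 dtbc_tertile 1.560835 1.14267 2.132029 0.0051394
logrank(co$os_time, co$os_event, co$dtbc_tertile)
#> $chi2 11.25  $df 2  $p 0.0036
```

At this seed the selected model keeps the DTBC tertile and age; the
cross-validated AUC is honestly lower than the apparent one because
selection is repeated inside each fold; and a higher DTBC tertile carries
a hazard ratio of 1.56 per tertile for overall survival. Decision curves
come from `decision_curve(co$node_binary, list(model = predict(m)))`.

A shell front end wraps the same functions:

```sh
Rscript inst/cli/dtbc.R score --image slide.tiff --roi slide.geojson \
        --mpp 0.22 --config params.yaml --out result.json
Rscript inst/cli/dtbc.R demo --seed 1 --out demo_out
```

(subcommands: `score`, `sweep`, `simulate`, `riskmodel`, `dca`,
`survival`, `demo`).

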