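# icgquant

Quantitative analysis of indocyanine green (ICG) fluorescence-angiography
time–intensity curves, for researchers studying perfusion-based tissue
characterisation (e.g. discriminating cancer from benign neoplasia and
healthy tissue in near-infrared surgical video).

After an intravenous ICG bolus, a region of interest (ROI) in an NIR video
yields a time–fluorescence curve: inflow to a peak, then washout. Malignant
tissue retains ICG, so its normalized post-peak downslope

    ds_N = (F(t_peak + N) − F(t_peak)) / N        (F peak-normalized to 1)

is much shallower than in healthy tissue (≈ −0.001 s⁻¹ vs ≈ −0.0065 s⁻¹ at
N = 10 s). `icgquant` implements the full analysis chain around this idea:

* **Simulation** — cohorts of ROI curves from a gamma-variate inflow /
  plateau-plus-exponential washout model `F(t_peak+Δt) = P·[p + (1−p)e^(−kΔt)]`,
  with class presets anchored to characteristic outflow slopes, acquisition
  artifacts (detector saturation, double-bolus twin peaks, movement noise),
  interrupted recordings, and rendered greyscale frame stacks.
* **Extraction** — mean-intensity "digital biopsy" traces from frame stacks
  with box ROIs; CSV and multi-page TIFF I/O.
* **QC** — saturation-plateau and twin-peak detection via topographic peak
  prominence.
* **Conditioning** — Savitzky–Golay smoothing, then peak normalization
  (removing camera-distance intensity differences).
* **Milestones** — time to first peak, time to half-max, time ratio,
  upslope, downslopes at 10–400 s horizons, kurtosis; horizons beyond the
  recording are explicitly missing.
* **Imputation** — K-nearest-neighbour within training tables; exponential
  tail-fit extrapolation `a·e^(−bΔt) + c` for single test curves.
* **Classification** — stratified five-fold cross-validated two-way
  (cancer vs not) and three-way AUC-ROC with fold-local imputation (no
  leakage), a fixed candidate set (bagged-KNN ensemble, logistic
  regression, random forest) tuned by inner CV, an incremental-downslope
  feature experiment, and a truncation-and-impute inference simulation.

## Worked example

```r
library(icgquant)

cohort   <- generate_cohort(cohort_config(seed = 1))   # 251 ROIs, 37 patients
features <- build_feature_table(cohort$traces)         # smooth -> normalize -> milestones

missingness_summary(features)
#>  ds10  ds50 ds100 ds200 ds300 ds400
#>     0     0     0    11    72   106

round(tapply(features$ds10, features$class, mean), 5)
#>   benign   cancer  healthy
#> -0.00387 -0.00169 -0.00698

report <- run_cv(features, experiment_spec("two_way", seed = 1),
                 traces = cohort$traces)
report
#> <classification_report> two_way, horizon 400 s, imputed
#>   mean AUC-ROC 0.993 (folds: 1.000, 0.988, 0.997, 1.000, 0.981)  classifier random_forest  n=251  imputed cells 945
```

The cohort reproduces the interrupted-series profile by construction (11,
72 and 106 ROIs end before the 200, 300 and 400 s downslope horizons; all
reach 100 s), the class mean 10-s downslopes sit near their presets
(−0.0065 / −0.004 / −0.001 s⁻¹), and cross-validated two-way classification
reaches mean AUC-ROC 0.993, with every missing cell filled fold-locally
(KNN for training rows, per-trace exponential fits for test rows).

The truncation experiment — keep only 10 s of post-peak data everywhere,
impute the rest, re-classify:

```r
ts <- truncation_inference_simulation(features, cohort$traces,
                                      spec = experiment_spec("two_way", seed = 1))
ts
#> <truncation_report> keep 10 s post-peak
#>   full-data mean AUC 0.993  truncated+imputed mean AUC 0.991  (drop 0.002)
```

A thin CLI covering simulate / extract / qc / features / classify lives at
`inst/cli/icgquant.R` (installed under `system.file("cli", package = "icgquant")`).

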