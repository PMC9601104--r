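# radrobust

How much segmentation accuracy do MRI radiomic biomarkers actually
need? In radiotherapy of brain metastasis, delta-radiomic models
predict each lesion's local outcome — local control (LC) versus local
failure (LF) — from the relative change of quantitative image features
between the baseline scan and the first follow-up. Every feature is
computed inside a tumour mask and its 5 mm peritumoural margin, so
replacing expert manual contours with automatic segmentations raises a
concrete question: at what Dice level do the selected biomarkers, the
outcome model, and the downstream survival stratification start to
break?

`radrobust` implements the full chain needed to answer that question at
desk scale, with synthetic imaging cohorts standing in for patient MRI
and controlled mask degradation standing in for segmentation networks
of different accuracy:

* **Synthetic cohorts** — seeded, paired baseline/follow-up two-channel
  (T1w + T2-FLAIR-like) volumes; class-dependent lesion growth and
  texture change; outcome-linked exponential survival
  (`cohort_config()`, `generate_cohort()`).
* **Mask engine** — Dice, Hausdorff distance, volume estimation error;
  `perturb_to_target_dice()` degrades a mask until its Dice against
  ground truth hits a prescribed target within ±0.01.
* **Cascaded segmenter** — slice-mask OR-reduction, component centring,
  nested crops, probability-map fusion over pluggable backends
  (`run_cascade()`).
* **Radiomics** — exactly 3436 features per lesion-timepoint: 19
  first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM per
  image (original + 8 stationary wavelet sub-bands), per modality (T1,
  T2) and per ROI (tumour, 5 mm margin), plus 26 shape features per
  ROI; delta features as `(FU1 − BL)/max(|BL|, ε)`
  (`extract_feature_vector()`, `delta_features()`).
* **mRMR selection** — greedy quotient criterion, F-statistic
  relevance / mean |Pearson| redundancy, 7 features from the training
  split (`mrmr_miq_select()`).
* **Outcome model** — Gaussian-kernel SVM solved exactly via the dual
  (C = 1, γ = 1/n_features, inverse-frequency class weights), train-set
  min–max normalization, confusion metrics + rank AUC (`train_svm()`,
  `evaluate_model()`).
* **Survival** — Kaplan–Meier curves and the log-rank test over test
  patients stratified by predicted outcome: cohort 2 = patients with at
  least one predicted-LF lesion (`km_curve()`, `logrank_test()`,
  `stratify_cohorts()`).
* **Experiment driver** — the paired robustness study across a ladder
  of Dice targets (`run_experiment()`, `write_report()`).

## Worked example

One seed of the robustness study on a 52-patient synthetic cohort
(24 train / 2 validation / 26 test), comparing ground-truth masks with
masks degraded to Dice 0.90, 0.85 and 0.80:

```r
library(radrobust)
report <- run_experiment(
  config = cohort_config(n_train_patients = 24, n_val_patients = 2,
                         n_test_patients = 26, seed = 101),
  levels = quality_levels(target_dice = c(NA, 0.90, 0.85, 0.80)),
  seed = 101)
print(report)
#> <robustness_report>
#>   ground_truth  dice 1.000  overlap 7/7  AUC 1.000  acc 100.0%  logrank p 0.00718
#>   dice_0.90     dice 0.890  overlap 0/7  AUC 0.905  acc 85.0%  logrank p 0.0471
#>   dice_0.85     dice 0.840  overlap 0/7  AUC 0.908  acc 82.5%  logrank p 0.45
#>   dice_0.80     dice 0.790  overlap 0/7  AUC 0.806  acc 75.0%  logrank p 0.143
```

Reading the rows: `dice` is the achieved mean Dice of the degraded
masks (follow-up masks carry a −0.02 offset, hence 0.890 for the 0.90
level); `overlap` counts how many of the 7 mRMR-selected delta features
coincide with the ground-truth selection; `AUC` and `acc` are test-set
lesion-level prediction quality; `logrank p` compares progression-free
survival between the predicted-LF and predicted-LC patient cohorts.
The qualitative pattern is the one the package is built to measure:
prediction and stratification hold up near Dice 0.9 and erode toward
Dice 0.8. The identity of the selected features is the most fragile
layer — at this scaled-down training size (~36 lesions) single-seed
overlaps routinely drop to 0 even at high Dice, and only the seed-mean
trend is meaningful (the acceptance suite checks exactly that trend
over five seeds).

`write_report(report, "results/run-101")` serializes the full report
(`report.json`) plus three CSV tables: achieved mask quality per level,
selected features per level with a `shared_with_ground_truth` flag, and
the metric table (Accuracy, Sensitivity, Specificity, AUC, F1, log-rank).

A command-line front end with `simulate` / `run` / `mrmr` / `survival`
subcommands lives at `inst/cli/radres.R`.

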