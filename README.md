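# fractacomp

Fractal analysis of CT body composition for metabolic-syndrome modelling.

Conventional CT body-composition metrics stop at tissue volumes. This
package quantifies the *spatial patterning* of segmented lower-extremity
tissues — skeletal muscle (SM), subcutaneous adipose tissue (SAT) and
intramuscular adipose tissue (IMAT) — with 3D box-counting fractal indices,
and combines them with volumetric indices and clinical covariates in a
logistic diagnostic-model workflow for metabolic syndrome (MetS). It is
aimed at imaging researchers who have tissue masks (e.g. from a
semi-automated segmentation) and want reproducible spatial-complexity
features plus a principled screen → prune → model → evaluate chain.

## The indices

For a binary mask tiled by cubical boxes of edge ε (fixed grid, partial
edge boxes included), with N(ε) the number of boxes containing foreground:

* **Fractal dimension**: the slope FD of the OLS fit
  `log N(ε) = FD · log(1/ε) + c`. Solid tissue → 3; isolated voxels → 0;
  the level-3 Menger sponge → `log 20 / log 3 ≈ 2.7268` (verified
  analytically in the tests).
* **Lacunarity Λ**: mean over scales of `σ²[M(ε)] / μ[M(ε)]²`, where M(ε)
  are the foreground masses of occupied boxes (population variance).
  Quantifies gappiness/heterogeneity; 0 for homogeneous tilings.
* **Multifractal range ΔFD**: `|slope_lower − slope_upper|` of the two
  half-range log–log fits. 0 for a pure power law; positive when scaling is
  scale-dependent (e.g. coarse marbling).

Each index is computed per tissue and per leg (legs found by 3D
connected-component labelling), then averaged across legs. Volumetric
indices are height-normalized (SMI, SATI, IMATI in cm³/m³) with ratios
IMR = IMATI/SMI, MSR = SMI/SATI, ISR = IMATI/SATI.

## Worked example

Measure a synthetic two-leg CT phantom with known ground truth, then build
and evaluate the three diagnostic models on a synthetic cohort:

```r
library(fractacomp)

ph <- leg_phantom(imat_fraction = 0.25, cluster_mm = 3, seed = 7)
pp <- preprocess_volume(ph$volume, ph$muscle_compartment, ph$subcut_compartment)
pp$masks
#> <tissue_mask_set> 92x45x40 grid: SM 44841, SAT 30255, IMAT 10871 voxels

subject_volumetrics(pp$legs$left, pp$legs$right, height_m = 1.68)
#> <body_composition_indices> SMI 9.5, SATI 6.4, IMATI 2.3 cm3/m3; IMR 0.242, MSR 1.482, ISR 0.359

fr <- subject_fractal_features(pp$legs$left, pp$legs$right)
round(as.numeric(fr[c("imat_fd", "imat_lacunarity", "imat_mfr")]), 4)
#> [1] 2.1112 0.5911 0.6115
```

The phantom's marbled IMAT has a fractal dimension well below 3 (it does
not fill the muscle core), nonzero lacunarity (gappy texture) and a clearly
positive multifractal range (coarse 3 mm marbling breaks pure power-law
scaling). The IMR of 0.242 is close to the requested IMAT fraction.

```r
cohort <- synth_cohort(default_cohort_spec(n = 184), seed = 8)
sp <- split_cohort(cohort, 0.7, seed = 8)          # 129 train / 55 test
models <- build_three_models(sp$train)
models$combined
#> <model_fit> outcome 'mets_label', n = 129
#>                  OR            CI        p
#> triglyceride  3.461   1.744-6.868 3.83e-04
#> diabetes     41.752 8.888-196.131 2.27e-06
#> imr           2.178   1.150-4.126 1.69e-02
#> imat_fd       4.574   2.251-9.294 2.63e-05
#> imat_mfr      3.469   1.738-6.923 4.20e-04

tr <- evaluate_model(models$combined, sp$train)
te <- evaluate_model(models$combined, sp$test, threshold = tr$threshold)
sprintf("combined AUC: train %.3f, test %.3f", tr$auc, te$auc)
#> [1] "combined AUC: train 0.925, test 0.836"
```

The cohort generator draws the outcome from a known logistic model over
triglyceride, diabetes history, IMR, IMAT FD and IMAT ΔFD, so the fitted
odds ratios above recover the generative signal (per SD for continuous
predictors), and the combined model outperforms the purely clinical one by
construction.

An end-to-end simulated run — phantom generation → preprocessing →
volumetrics → fractal features → model building → evaluation, with all
outputs, seeds and a config hash written to disk — is one call:

```r
run_pipeline(pipeline_config(out_dir = "run1", n_subjects = 40, seed = 1))
```

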