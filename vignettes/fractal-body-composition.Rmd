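---
title: "Fractal analysis of CT body composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal analysis of CT body composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractacomp)
```

## The problem

Body composition of the lower extremities — skeletal muscle (SM),
subcutaneous adipose tissue (SAT) and intramuscular adipose tissue (IMAT) —
is routinely quantified from CT by volume alone. Volumes miss *how* fat is
distributed: two muscles with the same IMAT volume can differ radically in
how finely the fat threads through the muscle fascia, and that spatial
pattern is what correlates with metabolic dysfunction. `fractacomp`
quantifies the spatial patterning of segmented tissue masks with 3D
box-counting fractal indices and feeds them, together with conventional
volumetric indices and clinical covariates, into a logistic
diagnostic-model workflow for metabolic syndrome (MetS).

## Fractal indices of a binary mask

A binary mask is tiled with a fixed grid of cubical boxes of edge
$\varepsilon$ voxels, anchored at the array origin, partial edge boxes
included. With $N(\varepsilon)$ the number of boxes containing at least one
foreground voxel:

* **Fractal dimension (FD)** is the slope of the ordinary least-squares fit
  $\log N(\varepsilon) = \mathrm{FD}\cdot\log(1/\varepsilon) + c$
  (natural logarithms; the slope is base-invariant). A solid block gives
  FD = 3, a single voxel FD = 0, and the level-3 Menger sponge
  FD $= \log 20 / \log 3 \approx 2.7268$ — all of which the test suite
  verifies analytically.
* **Lacunarity** ($\Lambda$) is the mean over scales of
  $\sigma^2[M(\varepsilon)] / \mu[M(\varepsilon)]^2$, where
  $M(\varepsilon)$ is the foreground mass of an *occupied* box and the
  variance is the population variance over occupied boxes. Homogeneous
  tilings give $\Lambda = 0$; gappy, heterogeneous patterns give large
  $\Lambda$. No $+1$ offset is added.
* **Multifractal range** ($\Delta$FD) splits the ascending scale list into
  a lower and an upper half (the middle scale is shared when the count is
  odd, so both half-fits have at least two points) and reports the absolute
  difference of the two half-fit slopes. A pure power law gives
  $\Delta\mathrm{FD}=0$; scale-dependent structure gives positive values.

Per subject, each index is computed per tissue for the left and right leg
separately and averaged.

### Numerical choices

* **Scale set**: powers of 2 from 1 to $\lfloor\min(\text{shape})/4\rfloor$,
  so the coarsest box still tiles the shortest axis four times; at least
  four scales are required (two per half-fit), hence a minimum mask extent
  of 32 voxels. For the Menger fixture, powers of 3 are passed explicitly
  so the grid aligns with the self-similar structure.
* **Single grid offset**, no offset averaging: deterministic and fast, and
  the translation-invariance test (shifts by multiples of every box size)
  documents exactly which invariance holds.
* **Fixed-grid lacunarity** (not gliding-box), occupied boxes only,
  population variance: this reuses the box-count pass and keeps
  $N(\varepsilon)\,\mu[M(\varepsilon)]$ exactly equal to the foreground
  count, an invariant asserted at every scale.
* **Degenerate profiles**: if all counts are equal the FD fit is flagged
  (`r_squared = NA`) and FD is 0; an empty mask is a hard error rather than
  a silent zero, so degenerate features cannot leak into models.

## Preprocessing

CT volumes are resampled to isotropic voxels (default 1 mm; images
trilinear, masks nearest-neighbour so they stay binary) because cubical
boxes require cubical voxels. Gaussian smoothing (default $\sigma$ = 1 mm,
symmetric-reflection boundaries) suppresses scanner noise. HU values are
normalized by an **additive** global shift that brings the median HU inside
the muscle compartment to a reference (default 50 HU): inter-scanner HU
offsets are approximately additive, and the median is robust to the fat
voxels inside the compartment. Tissue masks are then HU thresholds within
anatomically delineated compartments: voxels in the muscle compartment in
the muscle range (default $[-29, 150]$ HU) become SM, in the adipose range
(default $[-190, -30]$ HU) become IMAT; adipose-range voxels in the
subcutaneous compartment become SAT. IMAT is thus operationally defined as
adipose-range voxels inside the muscle compartment. Disjoint compartments
and disjoint HU ranges make the three masks mutually exclusive by
construction. Defaults are the widely used CT body-composition windows and
are exposed as configuration.

Bilateral masks are split into legs by 26-connected component labelling of
the mask union (requiring exactly two dominant components), not by a
midline cut, so off-centre positioning cannot split a leg in two.

## Volumetric indices

Tissue volumes (cm³, summed over both legs) are normalized by height cubed
(m³): SMI, SATI, IMATI, with ratios IMR = IMATI/SMI, MSR = SMI/SATI,
ISR = IMATI/SATI. Indices describe the subject, not one leg. A ratio with a
zero denominator is reported as missing rather than zero so it cannot bias
the downstream screen.

## Diagnostic-model workflow

The outcome label follows the IDF MetS definition: a central-obesity gate
(waist at or above a sex-specific cutoff, default 90 cm men / 80 cm women,
or BMI > 30 kg/m²) plus at least two of the glucose, blood-pressure,
triglyceride and HDL-C criteria (history/treatment flags count). The
cohort is split 7:3 into training and test sets, stratified by outcome with
per-stratum round-to-nearest (93/91 strata reproduce 129/55).

Model building is screen → prune → fit:

1. **Univariate screen**: one logistic fit per candidate; continuous
   predictors are z-scored on training statistics so odds ratios are
   per SD; retention at $p < 0.1$.
2. **Collinearity pruning**: iteratively remove variables while any VIF
   exceeds 10 *or* any pairwise Spearman $|r|$ exceeds 0.8 (highest VIF
   first; within an offending pair, the member with the larger univariate
   $p$). The OR-coupling is deliberate — an exactly duplicated column drives
   $|r|$ and VIF to their caps simultaneously and must be removable — and
   an AND variant is available as an option.
3. **Three models** on the same training data: *clinical* (pruned clinical
   candidates), *radiological* (exactly IMR + IMAT FD + IMAT multifractal
   range) and *combined* (their union), each a maximum-likelihood logistic
   fit with Wald standard errors. Non-convergence and separation are
   explicit failures, never silent output. If the screen retains no
   clinical candidate, the clinical model degrades to intercept-only and
   says so.

Evaluation: rank-based (Mann–Whitney, ties half-credit) AUC; the operating
threshold is chosen by the Youden index on training data only and frozen
for test/validation; calibration uses ten equal-width probability bins;
decision-curve analysis reports net benefit
$TP/n - (FP/n)\,p_t/(1-p_t)$ on a 0.01–0.99 grid against treat-all and
treat-none. Segmentation reliability uses ICC(2,1) — two-way
random-effects, absolute agreement, single measurement — with an F-based
95% CI; absolute agreement is the right form when two raters' volumes must
be interchangeable, not merely proportional.

## Synthetic data: what it emulates, what it does not

The package is validated on generated data with known ground truth:

* `menger_sponge()` and `random_cantor_3d()` provide analytic and
  stochastic fixtures whose dimensions are known in closed form
  ($\log 20/\log 3$ for the sponge; $\log 27p/\log 3$ in expectation for
  retention probability $p > 1/27$).
* `leg_phantom()` builds two cylinders with a SAT annulus, a muscle core
  and IMAT marbling: a Gaussian noise field smoothed to a chosen
  correlation length (`cluster_mm`) and thresholded at the quantile that
  yields the requested IMAT fraction. Fraction and spatial scale are
  therefore independently tunable. The marbling handle is meaningful for
  correlation lengths between roughly 1.5 voxel widths and half the core
  radius: below that the thresholded field degenerates to uncorrelated
  salt-and-pepper dust (whose scaling departure is dominated by the finest
  box size), above it the strands approach the compartment size. Within
  that regime the measured IMAT $\Delta$FD rises monotonically with
  `cluster_mm`, which is what makes spatial-pattern recovery testable
  end-to-end; the tests exercise cluster scales of 2, 3 and 5 mm with 20
  seeds each.
* `synth_cohort()` draws covariates from scenario means/SDs resembling a
  two-group MetS screening cohort (scenario parameters, not data) and draws
  the outcome from a stated logistic model over standardized features, so
  coefficient recovery and CI coverage can be measured exactly.

None of the phantoms simulate CT physics (beam hardening, scanner noise
correlation, reconstruction kernels), anatomical shape variation, or
segmentation error; the cohort generator draws covariates independently, so
it does not reproduce real-world correlation structure between, say, BMI
and waist circumference. Passing tests therefore demonstrate that the
algorithms compute what they claim on known ground truth — not that the
pipeline's diagnostic performance transfers to clinical data.

## Problem sizes and determinism

Simulation-based checks use deliberately modest sizes chosen for tight
ground-truth control: phantoms of roughly $90\times45\times40$ voxels,
random masks up to $32^3$ for the brute-force oracle comparisons, 20 seeds
per Monte-Carlo condition, cohorts of 184–500 subjects and 200 replicates
for coverage. Every generator takes an explicit seed and is bit-reproducible
given one; the end-to-end pipeline writes its seed and config hash into
every output.

## Known limitations

* Anatomical compartments (muscle envelope, subcutaneous shell) are inputs;
  the package does not segment them.
* Volume I/O is NIfTI; no DICOM ingestion.
* Single-offset box counting slightly overestimates counts for masks not
  aligned with the grid; the effect is deterministic and shared by all
  subjects on a common grid.
* The lacunarity of very sparse masks at fine scales is dominated by
  single-voxel boxes and should be interpreted jointly with FD.
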