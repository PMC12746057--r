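---
title: "Methods: predicting vestibular schwannoma growth from structural and DCE-MRI radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting vestibular schwannoma growth from structural and DCE-MRI radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vsgrowth)
```

# Scope and model

`vsgrowth` predicts whether a newly diagnosed, conservatively managed
vestibular schwannoma will grow, from imaging available at diagnosis:
a T2-weighted volume and the three microvascular parameter maps
(`Ktrans`, `ve`, `vp`) derived from DCE-MRI via the extended Tofts model
(ETM). The target label comes from longitudinal volumetry: growth vs
nongrowth (stable or regressing), decided by a patient-specific
volume-dependent threshold applied to consecutive follow-up scans.

The pipeline is deliberately classical — radiomic features plus a
cross-validated SVM — because cohorts of this disease are small (on the
order of a hundred patients), which rules out representation learning. All
stages are deterministic given a seed.

## Pharmacokinetic model

The two-compartment ETM gives the tissue contrast concentration

$$C_t(t) = v_p\,C_p(t) + K^{trans}\!\int_0^t C_p(u)\,
  e^{-k_{ep}(t-u)}\,du,\qquad k_{ep} = K^{trans}/v_e,$$

with $C_p$ the arterial input function (AIF). Assumptions: fast water
exchange, a single well-mixed plasma and EES compartment per voxel, a known
population AIF, and accurate pre-contrast T1 (here from variable-flip-angle
SPGR mapping). Units: rate constants in min^-1, time grids in seconds at
every interface (converted once internally), concentrations in mM.

Numerical choices:

* **Convolution** by trapezoidal discretization on the acquisition grid —
  grid-native, validated in the tests against adaptive quadrature to 0.1 %.
* **AIF**: a biexponential population decay with a smooth bolus-arrival
  upslope $1 - e^{-\tau/\mathrm{rise}}$ (default rise 0.08 min). A hard step
  at onset would make the trapezoidal convolution first-order inaccurate in
  the frames around arrival; the upslope is also the physically realistic
  shape. Any nonnegative `vs_aif` can be substituted.
* **Fitting**: bounded Levenberg–Marquardt on $(K^{trans}, v_e, v_p)$ with
  bounds $[0,2]$ min^-1, $[10^{-3},1]$, $[0,0.5]$ — wide enough to enclose
  all plausible schwannoma values with margin. Initialization from the
  linear least-squares ETM reformulation
  ($C_t = B_1\!\int\!C_p - B_2\!\int\!C_t + B_3 C_p$); midpoint-of-bounds on
  failure; an L-BFGS-B fallback (flagged) if LM errors; an all-zero curve
  returns $K^{trans}=v_p=0$ with $v_e$ flagged unidentifiable rather than a
  silent number. Tests assert the fit is never worse (RMSE) than a
  0.01-resolution grid search.
* **Signal inversion**: SPGR is inverted frame-by-frame for $T_1(t)$ using
  $M_0$ from the baseline frames and T10; out-of-range signals are clipped
  and counted, never silently accepted. The baseline frames must precede
  contrast onset — with the default 6 s grid and a 30 s onset, five baseline
  frames fit.

## ROI conditioning

Cystic components are removed (set difference) before perfusion analysis
because cysts lack cellularity and microvascularity. The remaining mask is
eroded with a 3×3 4-connected cross. We interpret the erosion as
**in-plane (slice-wise)**, since the partial-volume effects it guards
against are dominated by in-plane DCE resolution; a 3D 6-connected variant
is available (`planes = FALSE`). Erosion is intentionally not idempotent —
it trims one boundary ring per application. Mask projection between grids is
nearest-neighbour on axis-aligned grids; computing the registration
transform itself is out of scope. Z-score normalization defaults to the
nonzero image support as reference region (configurable), and refuses
zero-variance references.

## Growth labeling

The threshold of significant relative volume change decreases with tumor
volume. The published closed form behind the clinical calculator is not
reproduced here; instead the default is a clamped power law
$\theta(V) = \mathrm{clamp}(aV^{-b}, 0.05, 0.30)$ with $(a,b)$ solving
$\theta(0.2\,\mathrm{cm}^3)=0.30$ and $\theta(2.3\,\mathrm{cm}^3)=0.05$ —
the interquartile endpoints of the cohort's baseline volumes — so that the
threshold spans the documented ≈5–30 % range over the realistic volume
range. Any non-increasing function can be injected (`threshold_model(fun=)`).

Labels: growing (shrinking) requires exceeding $+\theta$ (falling below
$-\theta$) **relative to the diagnosis volume** on at least two consecutive
follow-up scans; otherwise stable. Fewer than two follow-ups yields
`undetermined`, which is excluded from training with a logged count — it is
not stable. If both patterns occur, growth takes precedence and the case is
flagged.

## Radiomics

Discretization uses a modality-dependent **fixed bin width**: the mean
within-ROI intensity range over the *training* patients divided by the
hyper-parameter `N_bins`; levels are min-anchored
(`floor((x - min)/w) + 1`), with no clipping or outlier exclusion, making
all texture features invariant to intensity shifts.

101 features per channel: 18 first-order, 8 shape, 24 GLCM, 16 GLRLM,
16 GLSZM, 5 NGTDM, 14 GLDM; shape features depend only on the mask and are
replicated across the four channels to keep the 4 × 101 accounting. Feature
order is frozen in `feature_manifest()`.

Conventions that change numbers and are therefore fixed as policy:

* 3D aggregation; GLCM/GLRLM use the 13 unique distance-1 directions with
  **feature values averaged over directions**; GLSZM zones and GLDM/NGTDM
  neighbourhoods are 26-connected.
* The gray-level axis spans 1..(max occupied level), keeping unoccupied
  levels — this affects nonuniformity features.
* Degenerate single-level ROIs take limit values (GLCM correlation and MCC
  are 1); NGTDM coarseness is capped at 1e6.
* GLDM dependence size is the dependent-neighbour count plus one, with
  tolerance α = 0 by default.
* Kurtosis is not excess-corrected; variance and skewness use population
  moments; first-order entropy/uniformity use the discretized histogram.
* The 8 shape features are volume, surface area, surface-to-volume ratio,
  sphericity, maximum 3D diameter, major axis length, elongation, flatness —
  the most standard eight, since the source accounting does not name them.
  Surface area uses a smoothed-isosurface (co-area) estimator
  $\int |\nabla G_\sigma * \mathbf{1}_{mask}|\,dV$ rather than voxel-face
  counting (which overestimates a sphere's area by ~50 %); tests hold it to
  within 5 % of the analytic sphere.

Every texture feature is checked against an independent brute-force
definition-summation oracle on random 6³ volumes at 1e-10 relative
tolerance. One caveat found this way: NGTDM *busyness* is **not** exactly
invariant to relabeling gray levels by +1 (its denominator
$\sum|i\,p_i - j\,p_j|$ depends on absolute levels); the difference-based
NGTDM features are.

## Prediction pipeline

Nested stratified 5-fold cross-validation (inner count also 5, a
documented choice — only "nested" is specified by the problem). Per outer
fold, strictly inside the training patients:

1. bin widths per channel (mean training ROI range / `N_bins`);
2. feature extraction; Z-score standardization (population SD; zero-variance
   or non-finite features dropped and logged);
3. top-k selection by two-group ANOVA F statistic (ties broken by the frozen
   feature order);
4. PCA to n components (training covariance; retained variance reported);
5. class-weighted SVM (balanced weights $N/(2N_{class})$, linear or
   gaussian kernel; gaussian bandwidth = `gamma_scale`/n-components).

Probabilities come from a logistic sigmoid fitted on **inner-CV out-of-fold
decision values** (Platt-style). This is a deliberate design: libsvm's
built-in probability training shuffles with uncontrollable RNG state, while
this construction is deterministic under the seed and avoids the optimism of
refit decision values. The Youden cutoff (prob ≥ cutoff ⇒ growth; ties to
the lowest cutoff) is computed on those training out-of-fold probabilities
and applied only to the corresponding validation fold.

Hyper-parameters (kernel, C, `N_bins`, k, n) are selected per outer fold by
inner-CV AUC over a configurable grid. The default grid centers on the
operating point `N_bins = 32, k = 100, n = 25`, gaussian kernel, with a
small C grid; `pipeline_grid()` builds arbitrary cross products (`n < k`
enforced). Wide grids multiply feature-extraction cost through the `N_bins`
axis, so the default is kept small; this is a scale choice, not a structural
one. One further efficiency decision: bin widths are fitted once per
**outer** training fold and reused by that fold's inner CV. Re-fitting
inside every inner fold would multiply extraction ~6-fold without changing
the leakage guarantee toward the outer validation fold, which never
contributes to any fitted statistic. A deliberately leaky variant
(`leak = TRUE`) exists solely so the tests can prove the guard binds
(outputs differ byte-wise); each fold also records `stat_fit_ids` for
instrumentation.

Ablation baselines reuse the identical pipeline on restricted inputs:
baseline volume only (selection and PCA bypassed), the 101 T2 features, or
the 54 first-order DCE-map statistics (18 × 3 maps).

## Evaluation

Fold-level metrics (AUC, AUCPR, accuracy, sensitivity, specificity at the
fold cutoff) are aggregated as mean ± SD; confusion/DOR/calibration are
*additionally* reported pooled over out-of-fold predictions, since summary
presentations of such models mix both conventions. DOR applies the Haldane
0.5 correction on zero cells, flagged. AUC is the rank-based Mann–Whitney
statistic (ties ½, verified against pair enumeration); AUCPR is average
precision with tied thresholds grouped. Calibration-in-the-large is defined
as observed event rate minus mean predicted probability; the calibration
curve uses 10 equal-width bins. Net benefit is
$TP/N - (FP/N)\,t/(1-t)$ with treat-all and treat-none references.
Rule-out (rule-in) operating points maximize specificity (sensitivity)
subject to a sensitivity (specificity) floor over observed thresholds, and
report infeasibility honestly. Model comparison uses a paired patient
bootstrap (N = 1000) of the AUC difference with percentile CI95 and
two-sided $p = 2\min(\Pr(\Delta\le 0), \Pr(\Delta\ge 0))$ floored at
$1/N$; single-class resamples are redrawn and counted. Permutation
importance is the mean AUC drop over 20 column permutations, signed by the
Spearman correlation with the predicted probability.

# The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised and tested:

* **n = 110** patients, growing prevalence 0.64 (exactly
  `round(n × prevalence)` growing);
* baseline volumes log-normal, median 0.7 cm³, log-SD 1.81 (fitted to the
  0.2–2.3 cm³ interquartile range), truncated to 0.05–15 cm³ — untruncated
  draws routinely exceed 50 cm³, which is not a plausible wait-and-scan
  tumor. Volumes are drawn **independently of class**, so a volume-only
  model must be uninformative on synthetic data;
* masks are voxelized ellipsoids with axis ratios uniform in [0.5, 1] on a
  1.5 mm isotropic grid (a common DCE-resolution grid; all channels are
  assumed coregistered and resampled); 21 % of tumors receive an interior
  spherical cyst;
* parameter maps are Gaussian random fields (white noise, Gaussian-smoothed
  at a class-specific correlation length, standardized, scaled, clipped to
  physical ranges). Class contrasts follow the directions observed in
  growing vs nongrowing tumors: higher mean `Ktrans`
  (0.15 vs 0.09 min^-1) and `vp` (0.046 vs 0.026), lower `ve` voxel
  dispersion (0.10 vs 0.22) with shorter correlation length (2.0 vs 4.5 mm),
  and smoother T2 texture in growing tumors. Between-patient SDs follow the
  same summary statistics. Only these directions (and the two printed means)
  are calibrated; per-feature effect sizes are emergent, not tuned;
* follow-up volumes at 12, 24 and 48 months: growing tumors follow
  exponential growth whose relative change exceeds the patient's threshold
  at every scan; 15/40 of nongrowing tumors regress analogously downward;
  the rest fluctuate within half the threshold. By construction every
  trajectory round-trips through `classify_course()` to its intended class —
  a property the tests assert over seeds;
* DCE series (optional, off by default since the pipeline consumes the maps
  directly — in the emulated study the maps were produced upstream) are
  forward-simulated per voxel through the ETM and SPGR models with additive
  Gaussian noise, so the kinetics module can be validated by round-trip.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: anatomical background and skull-base geometry,
scanner artifacts and motion, registration error between T2 and DCE grids,
segmentation variability, non-ellipsoidal tumor shapes, and any genuinely
unknown relationship between microvascular texture and growth. The
synthetic class separation is set by construction; cohort-scale AUCs on
synthetic data validate the machinery (leakage-free ranking, calibration,
nulls), not clinical performance.

# Problem sizes and runtime

The test and acceptance runs use the full 110-patient cohort for the
pipeline checks (per-fold re-extraction of 404 features across 5 folds), a
500-voxel SNR-20 Monte Carlo for map fitting, 20 random 6³ volumes for the
texture oracle sweep, and 1000 permutations/bootstrap replicates — sizes
chosen so the whole suite completes in minutes on one CPU while every
quantity is computed, never asserted from constants.

# Known limitations

* The LOAM threshold is a calibrated stand-in for the published calculator,
  injectable but not identical to it.
* The AIF is a population model; patient-specific AIF extraction, B1
  correction and motion correction are out of scope.
* Shape features use voxel/smoothed-isosurface estimators rather than a
  marching-cubes mesh; sphericity is accurate to a few percent at radii of a
  few voxels and degrades for very small masks.
* `e1071`/libsvm decision values are deterministic, but Platt scaling via
  `glm` can saturate on separable inner folds; probabilities are clipped to
  [1e-8, 1 - 1e-8].
* Real-cohort performance numbers are not reproducible from this package;
  they require the original patient data.
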