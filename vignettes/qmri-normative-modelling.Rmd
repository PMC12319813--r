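---
title: "Normative modelling of quantitative MRI in the basal ganglia: methods"
author: "qmrinorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of quantitative MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmrinorm)
```

## The problem

Quantitative MRI parameters — the longitudinal relaxation rate R1 (1/s),
the apparent transverse relaxation rate R2\* (1/s) and the tissue magnetic
susceptibility χ (ppm) — track myelin and iron content of brain tissue.
In the basal ganglia these parameters change systematically across
adulthood, so a raw measurement from one person is uninterpretable without
a reference: is a putaminal R2\* of 40 1/s high for a 30-year-old, normal
for a 70-year-old, or both? A *normative model* answers this by describing
the distribution of a metric as a function of age in a healthy reference
cohort, so that any new measurement can be expressed as a deviation
z-score. qmrinorm implements the full chain from quantitative maps to
deviation networks and patient-versus-control inference, together with a
seeded synthetic generator that reproduces the statistical structure the
analysis assumes, so every stage can be calibrated and tested end to end.

## The synthetic cohort generator

`generateCohort()` is first-class, tested code, not a fixture. Per ROI and
metric, it draws

value = intercept + βAge·age + βAge²·age² + βSex·sex + βHemi·hemi +
loading·latent + ε

with sex and hemisphere coded ±½ (centred coding: removing a fitted effect
moves every observation to the cohort average, which is what "correction
to the cohort mean" has to mean for a symmetric offset), ages uniform over
18–79 years (the reference cohort design is near-uniform by decade; the
exact sampling density is not critical to any property tested),
heteroscedastic noise ε ~ N(0, (σ₀ + σ′·(age − 18))²), and a per-subject
standard-normal latent factor shared by all ROIs of the same covariance
network. Two networks are built in — caudate + putamen, and the
pallidum/nigra/red-nucleus/subthalamic/ventral-pallidum group — mirroring
the two clusters of jointly fluctuating iron-rich nuclei that deviation
analyses of R2\* and χ reveal. Patient-group subjects receive an additive
shift per (ROI, metric), emulating the elevated nigral R2\*/χ of
Parkinson's disease.

The default parameter table (`defaultTrajectorySpecs()`) encodes the
qualitative shapes of healthy-ageing basal-ganglia qMRI: quadratic R1
trajectories peaking between 45 and 60 years (with the accumbens and
ventral pallidum as parabolic outliers that do not peak within the age
range), linear R2\* and χ increases strongest in putamen and nigra, small
sex and hemisphere offsets, and mild growth of the residual SD with age.
The values are illustrative magnitudes for 3T, chosen once; they are not
fitted to any dataset.

What the generator does *not* emulate: registration error, partial-volume
contamination, B0/B1 field structure, site effects, non-Gaussian outliers,
or age-dependent sampling density. Passing calibration tests on this
generator therefore demonstrates the correctness and calibration of the
*statistical machinery*, not robustness to every artefact of real data.

## MP2RAGE R1 estimation

`mp2rageForward()` implements the steady-state signal of the
double-inversion MP2RAGE sequence: inversion (efficiency 0.96 by default),
relaxation to TI1, a GRE block of `nReadout` excitations spaced
`readoutTR`, relaxation to TI2, a second GRE block, and relaxation to the
cycle end, solved in closed form by composing the affine maps of
longitudinal magnetisation over one period and taking the fixed point.
The two signals are read at the centre of each block. The sequence timing
printed on a protocol card (TI1/TI2/TR, flip angles) does not determine
the block structure, so `nReadout = 176` and `readoutTR = 7` ms are
explicit configuration with documented defaults suiting a 1 mm isotropic
readout; synthetic round trips are insensitive to this choice as long as
generation and matching share it.

Two estimators are provided:

* `dictionaryMatch()` — the B1-corrected fingerprinting-style method:
  unit-normalised signal pairs are simulated over an R1 × B1 grid
  (B1 step 0.005 of nominal) and each voxel picks the grid R1 maximising
  the absolute inner product with its measured pair, after selecting the
  B1 slice nearest the voxel's transmit-field estimate. The absolute
  inner product of unit vectors is the maximum-likelihood score under
  isotropic Gaussian noise with unknown complex scale, which is exactly
  the invariance the method needs: M0 and receive gain drop out. Ties
  resolve to the smaller R1.
* `lookupTableInvert()` — the conventional approach: invert the monotone
  UNI(R1) curve by interpolation. The UNI ratio folds back below roughly
  0.25 1/s at this protocol, so the default inversion range is
  [0.3, 4] 1/s and a non-monotone request is refused with guidance. The
  dictionary matcher has no such restriction — one of its practical
  advantages.

## Hybrid image and contrast matching

Registration of subcortical nuclei benefits from a joint contrast:
`computeHybrid()` computes μ0 + μ1·χ + μ2·R1norm with defaults
(0, 400, 1), where `normalizeR1()` maps the 1st–99th in-mask percentiles
of R1 linearly to 0–255 (percentiles use linear interpolation between
order statistics; a constant map is a degenerate histogram and an error).
`contrastMatch()` fits the polynomial (order 2 for R1, order 1 for χ)
mapping subject ROI medians to template medians, and
`deriveHybridCoefficients()` re-estimates the three hybrid weights from a
template's hybrid medians by OLS. ROI medians for matching use un-eroded
labels: erosion is a metrics-stage device against partial-volume effects,
not a registration device. Nonlinear registration itself is delegated to
external tools; this package implements the intensity mathematics only.

## ROI metrics

`roiStatistics()` reports the median, the interquartile range
(Q75 − Q25), and the bias-corrected Fisher–Pearson skewness
g1·√(n(n−1))/(n−2) — the small-sample correction matters because eroded
nuclei can be a few dozen voxels. Non-finite voxels are excluded and
counted. `erodeMask()` uses a 3×3×3 box element ("one voxel in all
directions" read literally, i.e. the 26-neighbourhood); it agrees with
the definitional oracle by construction and by test.

`fitSpatialGradient()` fits the first-order field
p0 + p1(x − x0) + p2(y − y0) + p3(z − z0) by OLS over an eroded ROI mask,
with coordinates in mm through the affine (RAS assumed) and (x0, y0, z0)
the mask's unweighted centre of mass, computed *after* erosion so the
centring matches the fitted voxel set. Right-hemisphere masks are
sign-flipped along x before fitting, so p1 runs lateral→medial in both
hemispheres and left/right gradients can be pooled under a common
convention; p2 and p3 are positive in the posterior→anterior and
inferior→superior directions. A planar mask leaves one direction
unidentifiable: the fit warns and flags that coefficient `NA` rather than
returning an arbitrary number. Gradient analysis is intended for the
putamen and caudate (smaller nuclei are too small relative to voxel size
for a stable fit) but is callable on any ROI with at least 8 voxels.

Volumes are normalised by intracranial volume and expressed as percentage
change about the population mean, 100·(V − V̄)/V̄, whose cohort mean is
zero by construction (`volumePercentChange()`).

## Covariate model and t→z conversion

`fitGLM()` fits value ~ 1 + age + age² + sex + hemisphere by OLS with
classical standard errors. Age enters raw and squared raw — the model is
stated in those terms, and the (documented) collinearity between age and
age² affects the interpretation of individual coefficients, not the
fitted mean or the corrected values. Hemisphere rows are treated as
independent observations at this stage, with the hemisphere regressor
absorbing the mean left–right difference; the within-subject correlation
this ignores is handled where it matters, in the group comparison (below).
`tToZ()` converts t to z through the sign-preserving quantile map
z = Φ⁻¹(F_t(t)), evaluated in log space so |t| in the hundreds still
yields finite, strictly monotone z. `residualize()` subtracts only the
fitted sex and hemisphere terms, leaving the age trajectory intact; an
external cohort is corrected with the *reference* cohort's betas.

## Gaussian-process normative model

`fitGPR()` standardises ages and values and fits an exact GP with a
linear + squared-exponential + white-noise kernel. The kernel family is
the deliberate choice here: the linear term captures the monotone R2\*/χ
trends without forcing the SE term to a huge length scale, the SE term
captures the curved (inverted-U) R1 trajectories, and the white term
separates measurement noise from trajectory structure. Hyperparameters
maximise the exact log marginal likelihood (L-BFGS-B with analytic
gradients, log-parameterised, 5 seeded restarts by default; box bounds
keep the length scale in [0.05, 50] standardised-age units and the noise
variance above 10⁻⁶). A 10⁻¹⁰ jitter stabilises the Cholesky.

The predictive SD *includes* the noise variance: z-scores describe where
a new observation falls relative to the population of observations, so
|z| ≤ 1.96 is a 95% band for individuals, which is how deviation scores
are read clinically. Reference-cohort scores use 10-fold cross-validation
(`zscoreCrossval()`): subjects are ordered by age and fold labels are
randomly permuted within consecutive blocks, so every fold spans the age
range and no fold model extrapolates; both hemisphere rows of a subject
share a fold, preventing leakage of subject-level effects. New cohorts
are scored against the frozen full-data model (`zscoreApply()`), which
refuses values not flagged as corrected.

The noise term is homoscedastic. The generator's age-growing variance is
therefore mildly misspecified at the model stage — the posterior SD still
varies with data density, but not with the true noise law. This is a known
limitation; calibration tests show the residual effect on coverage at the
default heteroscedasticity is within the tested band.

## Deviation correlations, networks, and group comparison

`corrMatrix()` computes pairwise-complete Pearson correlations of
z-scores (across metrics per ROI, or across ROIs per metric), flagging
cells with fewer than 3 complete pairs or zero variance.
`thresholdNetwork()` keeps positive correlations at or above a threshold
(0.4 and 0.6 are the conventional choices) and returns connected
components — negative correlations are not evidence of a shared
deviation process, so they never form edges.

`compareGroups()` runs Welch t-tests per (ROI, metric, statistic) cell —
Welch rather than pooled-variance because group sizes like 44 versus 316
make equal-variance assumptions gratuitous — and adjusts with
Benjamini–Hochberg within each (metric, statistic) family of ROIs. The
two hemisphere rows of a subject are averaged before testing: they share
subject-level variance (the latent network factor in the generator; any
subject-level biology or bias in real data), and treating them as
independent inflates the evidence by roughly √(1+ρ). With pooling, the
null calibration of the comparison is nominal (measured sd(t) ≈ 1.04).

One property of BH worth keeping in mind when reading results: it
controls the false-discovery *rate*, not the familywise error. When a
family contains genuine discoveries, a null ROI's raw p-value only needs
to undercut a step-up threshold of roughly (rank·q/m) to be dragged
along, so with two true effects in a six-ROI family an occasional
borderline false flag (adjusted p just under 0.05) appears in about one
family in ten even with perfectly calibrated tests. Requiring zero false
flags across repeated studies would need familywise control (e.g.
Bonferroni–Holm), which is not the procedure used here.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation between order statistics throughout.
* Dictionary ties: smaller R1 wins; zero-norm voxels yield `NA` and are
  counted; out-of-grid B1 values are clamped with a warning count.
* GP optimiser failures on all restarts raise an error with diagnostics;
  near-zero value variance is refused rather than fitted.
* Erosion to an empty mask, empty ROIs, single-sex or single-hemisphere
  cohorts, collinear hybrid regressors and non-monotone lookup ranges are
  all explicit errors naming the offending object.
* All randomness flows from user-supplied integer seeds; identical
  (inputs, config, seed) reproduce identical outputs byte for byte.

## Problem sizes used by the test suite

The statistical tests run at the study's own scale: 260-subject reference
cohorts; 1000 simulated cohorts for GLM null calibration; a
260-train/2000-held-out split and 50 seeds for GP calibration and peak-age
recovery; 100 noisy phantoms for gradient recovery; 1000 replicates for
FDR calibration; and 20 seeds of the full control/applied
(44 + 316) detection experiment with 6 ROIs × 2 metrics. These sizes were
chosen to make the binomial noise of each pass/fail bound small relative
to its margin.

## Known limitations

* Trajectory parameters are illustrative, not fitted to any cohort.
* GP noise is homoscedastic; strongly age-dependent variance in real data
  would mis-calibrate tail z-scores at the age extremes.
* The GLM stage treats hemisphere rows as independent; only the group
  comparison pools them.
* Registration, skull stripping, QSM reconstruction and R2\* fitting are
  out of scope: the pipeline starts from quantitative maps.
* A z-score is relative to *this* reference cohort under *this*
  acquisition; models do not transfer across protocols without
  harmonisation.
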