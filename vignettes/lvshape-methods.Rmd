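---
title: "Statistical shape analysis of the left ventricle for arrhythmic risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape analysis of the left ventricle for arrhythmic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lvshape)
```

# The problem

In non-ischaemic dilated cardiomyopathy (DCM), remodelling of the left
ventricle (LV) — cavity dilation, wall thinning, loss of the ellipsoidal
profile — accompanies a substantial risk of ventricular arrhythmia and
sudden cardiac death. Scalar clinical measurements (ejection fraction,
sphericity index) compress the 3D anatomy into one number and discard most
of the remodelling signature. `lvshape` implements the alternative: describe
each patient's complete end-diastolic LV geometry as a point in a
high-dimensional shape space, learn the low-dimensional axes of anatomical
variation across a cohort by principal component analysis (PCA), and let a
sparse survival model decide which of those axes carry prognostic
information about future arrhythmic events.

The pipeline has five stages, each its own module:

1. **Synthetic cohort generation** — anatomy, outcomes and covariates with
   known ground truth, so that every downstream stage is testable without
   patient data.
2. **Mesh personalization** — fit a fixed-topology two-surface template to
   each patient's stack of short-axis epicardial/endocardial contours, then
   align the cohort rigidly.
3. **Geometry metrics** — cavity (blood-pool) volume, apex-to-base length,
   mean wall thickness, sphericity, and 16-segment bullseye maps.
4. **Statistical shape model** — PCA over the aligned shape vectors;
   projection, reconstruction, mode exaggeration, mode–variable
   correlations.
5. **Arrhythmic score and survival analysis** — Cox–Lasso with
   cross-validated partial likelihood yielding the LV arrhythmic shape
   (LVAS) score, followed by propensity-weighted and time-varying-covariate
   Cox models.

# Shape representation and personalization

## The lattice template

Each LV is a pair of surfaces (endocardium, epicardium) on a structured
lattice: one apex node plus `n_long = 16` rings of `n_circ = 24` nodes per
surface, ordered apex to base, giving a shape vector of length
$3 \times 2 \times (24 \times 16 + 1) = 2310$. The template is a truncated
half-ellipsoid: the endocardium is the cap of an ellipsoid with semi-axes
$(a, b, c)$ cut by the basal plane, and the epicardium is offset outward
along the exact ellipsoid normal by the wall thickness. Rings are spaced
uniformly in polar angle, which keeps facets well-shaped at the apex.

The lattice replaces the cubic-Hermite finite-element basis used in the
original reconstruction line of work. Downstream analysis needs exactly two
properties — smoothness and fixed cross-patient node correspondence — and
the lattice supplies both while keeping every operation (slicing, fitting,
PCA) elementary. Lattice resolution is configurable; all defaults in this
package use 24 × 16.

## Fitting

`fit_to_contours()` alternates two steps (ICP-style):

* **Correspondence.** Every contour point is matched to the surface point at
  the same slice height and circumferential angle, expressed as a bilinear
  combination of at most four lattice nodes. Points produced this way lie
  exactly on the faceted surface, so a noiseless stack rendered from a known
  mesh can be fitted to numerical precision.
* **Update.** Per surface, solve the linear least squares problem
  $\min_x \|Ax - b\|^2 + w\,\|L(x - x_0)\|^2$ where $A$ interpolates nodes
  to matched points, $L$ is the lattice graph Laplacian (degree-normalized)
  and $x_0$ the initialization. The Laplacian term propagates information
  into regions without contour support (apex cap, sub-slice gaps) and
  controls noise amplification.

Iteration stops when the RMS node change falls below $10^{-3}$ mm, when the
mean distance stops decreasing (the previous, better iterate is kept — this
guarantees the reported fit error is non-increasing over accepted
iterations), or at `max_iter = 100`.

**Smoothing weight.** The default `smoothing_weight = 0.3` was frozen from
an L-curve sweep on synthetic fixtures: over $w \in \{0.03, 0.1, 0.3, 1,
3\}$ the noiseless fit error grows from 0.002 to 0.085 mm while the
volume error stays flat near 0.8%; 0.3 sits at the elbow with comfortable
margins on both criteria used downstream (noiseless error < 0.1 mm,
jittered error below the in-plane voxel scale).

**Initialization.** The template is sized from the truncated stack: the
base sits a half-slice above the most basal slice; the apex is located by
extrapolating the squared apical cavity radius to zero (a fixed half-slice
margin carries a sawtooth bias of up to one slice thickness in the cavity
length, which both shortened every fitted mesh by ~4 mm and injected a
nonlinearity that degraded PCA coefficient recovery); mid-cavity diameters
come from second-moment matching of the mid slice and wall thickness from
the epi–endo mean-radius difference. The lattice is *oriented by the right-ventricular
(RV) landmark direction*, not by the contour principal axes: principal axes
are rotationally unstable on near-circular slices, and an unstable
orientation scrambles cross-patient node correspondence (we observed PCA
coefficient recovery collapse before adopting the landmark convention). The
landmark is precisely the device the imaging protocol uses to break the
LV's circumferential symmetry, so it is the natural cohort-consistent
frame.

## Alignment

Cohort alignment is rigid only: centre of mass to the origin, +z apex to
base (the slice normal), +x towards the RV landmark. No Procrustes scaling
is applied — size is part of the signal (the first shape mode is expected
to track end-diastolic volume).

# Geometry metrics

* **BPvol** — blood-pool (cavity) volume: divergence theorem over the
  triangulated endocardium closed by a basal fan cap; mm³ → mL.
* **Length** $L$ — epicardial apex to basal plane along z.
* **Mean wall thickness** — mean over endocardial lattice sites of the
  distance to the epicardium along the outward endocardial normal
  (ray-casting; robust to tangential correspondence sliding, unlike
  nearest-point). Sites whose ray misses are excluded with a warning; more
  than 10% missing is an error.
* **Sphericity** — $\mathrm{BPvol} / \left(\tfrac{4}{3}\pi (L/2)^3\right)$,
  the cavity volume relative to the sphere whose diameter is the LV length.
  Note: the source study prints an average-geometry sphericity of 1.63 that
  is inconsistent with this formula applied to its own printed volume and
  length (231.3 mL, 85.46 mm → 0.708) and with its cohort median of 0.63;
  this package follows the formula and makes no attempt to reproduce 1.63.
* **Bullseye** — 16 AHA-style segments (basal and mid sextants, apical
  quadrants; z-thirds; angles counter-clockwise from +x = RV direction).
  There is no 17th apex segment because the lattice apex cap is a single
  node.

All metrics operate on aligned meshes and are therefore invariant to rigid
repositioning of the input.

# The statistical shape model

PCA of the $N \times 2310$ matrix of aligned shape vectors, computed
through the $N \times N$ Gram matrix when (as always in practice)
$D > N$ — exact for the non-null spectrum. The model keeps
`n_retained = 10` modes for projection and scoring, chosen because ten
modes capture the bulk of anatomical variance at cohort sizes near 150,
while the full eigenvalue spectrum is retained for variance accounting.

PCA signs are arbitrary, so each mode is flipped to a convention: moving
along the mode increases cavity volume (fallback for volume-neutral modes:
largest-magnitude component positive). This makes serialized models
comparable across runs.

Mode–variable associations use Spearman correlation with the t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of
freedom, pairwise-complete; at $n = 156$ the implied two-sided 5%
significance threshold is $|\rho| \ge 0.157$.

# The LVAS score

## Cox–Lasso

The retained mode coefficients enter an L1-penalized Cox model maximizing
$\ell(\beta) - \lambda \sum_j |\beta_j|$, where $\ell$ is the partial
log-likelihood with the Efron tie correction (Efron rather than Breslow
because coarse follow-up times produce ties; with continuous synthetic
times the two coincide). The solver is cyclic coordinate descent on
successive quadratic approximations with warm starts along a log-spaced
grid of 100 penalties from $\lambda_{\max}$ (computed from the null-model
gradient; the smallest penalty with an all-zero solution) down to
$10^{-3}\lambda_{\max}$. Mode coefficients are standardized to unit
variance inside the fit — lasso penalties are scale-sensitive and the mode
variances span two orders of magnitude — and weights are reported on the
raw coefficient scale. Karush–Kuhn–Tucker optimality is verified at every
path point ($|g_j| \le \lambda$ for inactive, $g_j = \lambda\,
\mathrm{sign}(\beta_j)$ for active coordinates, tolerance $10^{-6}$).

## Penalty selection

The penalty maximizes the Verweij–van Houwelingen cross-validated partial
log-likelihood
$\mathrm{CV}(\lambda) = \sum_k \left[\ell(\hat\beta_{-k}) -
\ell_{-k}(\hat\beta_{-k})\right]$ over 10 folds stratified by event status
(fold assignment reseeded up to 5 times if a fold ends up without events).
Fold count and likelihood variant are configuration, since the original
study's supplement detailing them is not available; the values here are
field defaults.

**A note on null behaviour.** On pure-noise inputs the argmax of
$\mathrm{CV}(\lambda)$ sits at $\lambda_{\max}$ (an empty model) in a
majority of replicates (13/20 at $n = 156$ in our fixed-seed experiment),
with the remainder selecting small spurious supports. An idealized
expectation that the null model is selected in $\ge 80\%$ of replicates is
not achievable with plain argmax CV selection — cross-validation selection
is not a consistent null-model selector, and no parsimony rule (such as a
one-standard-error rule) is prescribed here. The test suite asserts the
computed behaviour.

## Normalization and quartiles

The raw score $\mathrm{raw}_i = \sum_j \beta_j c_{ij}$ is max–min
normalized to $[0, 1]$ with the *training* minimum and maximum frozen into
the model, so new patients are scored on the published scale (out-of-range
raw scores clip to $[0,1]$ with a warning). Orientation is inherited from
the Cox fit: higher score, higher hazard. Training quartile cutpoints are
stored; `quartile_code()` assigns 0–3 with ties to the lower quartile, and
the integer quartile enters Cox models as a continuous covariate — the
"hazard ratio per quartile" reporting convention.

# Survival analysis

* **Cox fits** delegate estimation to `survival::coxph` (Efron ties) behind
  the package's reporting contract; independent brute-force maximization on
  small instances is part of the test suite. Time-varying device covariates
  (ICD, CRT) are expanded by the package into counting-process episodes
  that split at implant time, switch 0 → 1 and stay on (absorbing; devices
  are not explanted), conserving each patient's follow-up exactly.
* **Screening** for the propensity model keeps variables with no missing
  data and univariate Cox $p < 0.25$, with age and sex always included.
* **Generalized propensity / IPW.** For the continuous LVAS exposure the
  conditional density $f(e \mid X)$ is modelled by a spline-based GAM
  regression with Gaussian residuals; the stabilized weight is
  $w_i = \hat f_{\text{marg}}(e_i) / \hat f(e_i \mid X_i)$, truncated at
  the 1st/99th percentiles. The original study's exact non-parametric
  estimator lives in an unavailable supplement; a tree ensemble was
  suggested, but no tree-ensemble package is available in this toolchain,
  and the GAM serves the same role (any flexible conditional-mean
  estimator with a residual density model). Both the weighted Cox fit
  (robust variance) and a sensitivity fit entering the propensity score as
  a covariate are reported. Balance diagnostics compare weighted and
  unweighted exposure–covariate Pearson correlations; under planted
  moderate confounding ($r \approx 0.37$) weighting reduces the
  correlation below 0.05. Stronger confounding shrinks the effective
  sample size and leaves residual imbalance — an intrinsic property of
  IPW, not an implementation artifact.
* **Multiple imputation** by chained equations: predictive mean matching
  (5 donors) for continuous columns, logistic draws for binary, 10 cycles,
  $m = 10$ imputations, the outcome (event indicator and log follow-up)
  among the predictors; Cox estimates pooled by Rubin's rules with
  Barnard–Rubin degrees of freedom.
* **Descriptive comparisons**: Mann–Whitney (normal approximation,
  tie-corrected) for continuous variables; $\chi^2$ with Yates continuity
  correction on 2×2 tables. Yates is chosen because it reproduces the
  published baseline-table p-value for sex (≈ 0.99; the exact corrected
  statistic on those counts is 0, hence $p = 1$, where the uncorrected
  test gives 0.78). No multiplicity adjustment is applied anywhere,
  matching the source analysis.

# The synthetic cohort: what it states and what it does not

`synthetic_truth()` fixes the generator's world:

* **Template geometry** — cavity volume 231.3 mL, epicardial apex-to-base
  length 85.46 mm, wall thickness 7.9 mm: the published average DCM
  geometry. The long semi-axis (85 mm) puts the basal plane just below the
  ellipsoid equator; the in-plane semi-axis (≈ 38.7 mm) is solved
  analytically from the cap-volume formula.
* **Planted modes** — three smooth orthonormalized deformation fields
  mirroring the dominant clinical directions: *size* (uniform dilation),
  *sphericity* (mid-cavity widening with long-axis shortening), and an
  *arrhythmic* direction (basal widening — the parabolic long-axis profile
  — plus basal-lateral epicardial thinning). Coefficient SDs (120, 60,
  25 mm in field-norm units) give a realistic end-diastolic-volume spread
  (≈ 30% SD) with size dominating, as in real cohorts. The thinning
  amplitude (0.35 of the widening term) keeps the wall positive out to
  ±3 SD while thinning the basal lateral wall by 2–3 mm, the scale seen in
  published bullseye maps.
* **Outcomes** — exponential event times with rate
  $h_0 \exp(\sum_k \theta_k c_k)$, $h_0 = 0.015$/yr, independent
  exponential censoring at 0.071/yr, administrative horizon 16 years. The
  planted effect is $\log$-HR 0.7 per SD of the arrhythmic coefficient and
  0 for the others. Marginally this yields ≈ 16% events and a median
  follow-up near 7.7 years at $n = 156$ — the published cohort's scale.
  ($h_0$ is set so the *marginal* event rate is 16% including the
  $E[e^{\theta c}] \approx 1.28$ inflation from the planted effect.)
* **Acquisition** — per-patient slice thickness uniform on 7–10.5 mm and
  in-plane resolution 1.3–2.2 mm (protocol ranges; resolution is metadata —
  contours are geometric, not rasterized). Contour-point jitter is
  isotropic Gaussian, redrawn per slice until the polygon is simple (iid
  jitter can fold a small apical polygon; real segmentation curves cannot
  self-intersect). One supra-basal "valve plane" slice is appended for the
  truncation step to remove.
* **Covariates** — marginals loosely matching the published baseline table
  (age ≈ 58, 82% male, LVEF ≈ 38%, …), MCAR missingness confined to
  smoking/AF/mitral-regurgitation columns, and an optional confounding map
  that adds covariate effects into the shape-coefficient generator.
  Censoring is independent of shape (standard non-informative censoring).
  All randomness flows from one master seed through named substreams.

A green pipeline test therefore establishes: the fitter reaches sub-voxel
accuracy on geometry of this class and noise level; PCA recovers planted
directions when they dominate variance; the Cox–Lasso recovers a sparse
planted support at realistic event counts; and IPW removes planted linear
confounding of moderate strength. It does **not** establish performance on
real segmentations (papillary muscles, breath-hold misregistration,
through-plane motion, observer bias are all absent), nor anything about the
published cohort's specific hazard ratios, which depend on non-public
outcome data.

# Numerical choices

* Facet discretization biases volumes low by ≈ 1.3% at 24 × 16 (inscribed
  polygons); analytic-volume tests use finer lattices, cohort-level tests
  compare like with like.
* Lasso coordinates with $|\beta| < 10^{-10}$ are snapped to exact zero —
  KKT-boundary coordinates otherwise retain float residue that corrupts
  support-based selection.
* The linear predictor is max-shifted before exponentiation in the partial
  likelihood (the shift cancels exactly between event terms and
  denominators).
* Quartile ties go to the lower quartile; degenerate all-equal scores land
  in quartile 0.
* Complete separation in Cox fits is flagged and the coefficient capped at
  ±15; constant covariates report HR 1 with infinite standard error.

# Known limitations

* The fit's z/θ correspondence assumes surfaces star-shaped about the long
  axis within each slice — true for LV anatomy, not for arbitrary shapes.
* Mean wall thickness near the basal rim depends on the ray convention;
  sites whose rays miss the epicardium (strong local thinning) are
  excluded, slightly biasing the mean upward in extreme geometries.
* The generalized propensity model assumes Gaussian residuals; heavy-tailed
  exposure residuals would call for a kernel density.
* With fewer events than folds, CV stratification fails by construction
  (reported as an error after 5 reseeding attempts).
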