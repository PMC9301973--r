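# lvshape

Statistical shape analysis of the left ventricle (LV) for arrhythmic risk
stratification in dilated cardiomyopathy (DCM).

## The problem

LV remodelling in DCM — dilation, wall thinning, loss of the ellipsoidal
profile — is linked to ventricular arrhythmia and sudden cardiac death, but
scalar measurements (ejection fraction, sphericity) discard most of the 3D
anatomical detail. `lvshape` implements a computational-anatomy pipeline
for cardiac-MRI cohorts:

1. **Reconstruction** — fit a fixed-topology two-surface template mesh
   (truncated half-ellipsoid; 24 x 16 lattice per surface, shape vector
   length 2310) to each patient's stack of short-axis
   epicardial/endocardial contours, then align the cohort rigidly (centre
   of mass, apex-base axis, RV-landmark direction; no scaling).
2. **Statistical shape model** — PCA over the aligned shape vectors
   `X_i ≈ X̄ + Σ_{j=1}^{10} c_ij M_j`, giving orthonormal modes `M_j` of
   anatomical variation, ordered by explained variance, with per-patient
   coefficients `c_ij` as candidate biomarkers.
3. **LVAS score** — an L1-penalized Cox model (coordinate descent, Efron
   ties, KKT-verified) on the mode coefficients, with the penalty chosen by
   the Verweij–van Houwelingen cross-validated partial likelihood, yields a
   sparse weight vector `β`. The LV arrhythmic shape score is the max–min
   normalized linear combination `LVAS_i = norm(Σ_j β_j c_ij) ∈ [0, 1]`,
   higher = worse shape, entered per-quartile into survival models.
4. **Confounding-controlled survival analysis** — univariate screening
   (complete data, Cox p < 0.25, age/sex forced), a generalized propensity
   score for the continuous exposure with stabilized inverse-probability
   weights, time-varying ICD/CRT device covariates in counting-process
   form, chained-equation multiple imputation with Rubin pooling, and
   Mann–Whitney / Yates-corrected chi-squared descriptive comparisons.
5. **Synthetic cohort generator** — first-class, tested code that emulates
   the motivating study's world (156 patients, 7–10.5 mm slices, ~16%
   events over up to 16 years, shape variance dominated by size and
   sphericity, a sparse planted "arrhythmic" direction with log-HR 0.7 per
   SD, optional covariate confounding and missingness), so the whole
   pipeline is testable with known ground truth and no patient data.

See `vignettes/lvshape-methods.Rmd` for the models, assumptions, numerical
choices, and what the synthetic world does and does not establish.

## Worked example

```r
library(lvshape)

# a small synthetic cohort with known ground truth; a more eventful world
# than the 16%-event default so the toy run has enough events to learn from
truth <- synthetic_truth(baseline_hazard_rate = 0.05)
coh <- generate_cohort(n = 80, truth = truth, seed = 7, noise_sd = 1)

# personalize the template to each contour stack and align
fitted <- lapply(coh$stacks, function(st) {
  st <- truncate_basal(st)
  align_mesh(fit_to_contours(initialize_template(st), st)$mesh)
})

# shape model and geometry of the average anatomy
model <- fit_pca(fitted, n_retained = 10)
co <- project_shape(model, do.call(rbind, lapply(fitted, flatten_mesh)))
model
geometry_metrics(reconstruct_shape(model, numeric(0), as_mesh = TRUE))

# learn and apply the arrhythmic shape score (5 folds: 33 events only)
lvas <- build_lvas(model, co, coh$cohort$follow_up_years, coh$cohort$event,
                   n_folds = 5, seed = 1)
s <- lvas_scores(lvas, co)
q <- quartile_code(s, lvas$quartile_cutpoints)
cox_fit(cbind(coh$cohort, lvas_q = q), "lvas_q")
cor(s, coh$true_coefficients[, "arrhythmic"])
```

Output from this exact script (seed 7):

```
shape_model: N=80, D=2310, 10 modes retained, first-10 variance 97.6%
     bpvol   length mean_wall_thickness sphericity
1 222.9619 84.94869            7.896972  0.6946435
lvas_model: modes {1, 2, 3, 4, 6, 7, 8, 10}, weights (-0.00405, 0.0002886,
  0.03531, -0.03979, -0.03222, -0.03888, -0.007506, -0.01255), lambda=2.968
Cox fit (Efron ties), n=80, events=33
 covariate               hr            p
    lvas_q 3.46 (2.17-5.53) 2.074322e-07
[1] 0.7513975
```

What the numbers mean: the mean synthetic anatomy measures ~223 mL cavity
volume, ~85 mm length and ~7.9 mm wall thickness — the
dilated-cardiomyopathy average geometry the generator states (231.3 mL /
85.46 mm / 7.9 mm) up to facet discretization and fit error. The learned
score is strongly associated with the arrhythmic endpoint per quartile and
correlates 0.75 with the planted arrhythmic-mode coefficient; at this toy
size the lasso keeps several nuisance modes with small weights, and the
acceptance suite checks sparse-support recovery at its stated scale
(n = 300, ~60 events, 20 replicates).

## Command line

```sh
lvshape simulate   --n 156 --seed 1 --out cohort_dir
lvshape fit-meshes --contours cohort_dir --out meshes
lvshape metrics    --meshes meshes --out metrics.csv
lvshape pca        --meshes meshes --out model.json --coeffs coeffs.csv
lvshape lvas-train --coeffs coeffs.csv --cohort cohort_dir/cohort.csv --out lvas.json
lvshape survival   --cohort cohort.csv --lvas scores.csv --model multi2 --out results.json
```

(the `lvshape` script lives in `inst/cli/`; equivalently
`Rscript -e 'lvshape::lvshape_cli()' <args>`).
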