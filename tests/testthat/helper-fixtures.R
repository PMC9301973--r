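# memoized fixtures shared across test files (built once per test run)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_truth <- function() fixture("truth", function() synthetic_truth())

# render -> truncate -> initialize -> fit -> align for a list of meshes
fit_pipeline <- function(meshes, noise_sd, seed) {
  res <- lapply(seq_along(meshes), function(i) {
    st <- truncate_basal(render_contours(
      meshes[[i]], slice_thickness = 8, noise_sd = noise_sd,
      seed = seed + i, n_supra_basal = 1L))
    ft <- fit_to_contours(initialize_template(st), st)
    list(mesh = ft$mesh, report = ft$report)
  })
  list(fitted = lapply(res, `[[`, "mesh"),
       reports = lapply(res, `[[`, "report"))
}

# n = 50 cohort at 1 mm jitter: fit quality and volume recovery checks
fx_small_cohort <- function() fixture("small_cohort", function() {
  truth <- fx_truth()
  sh <- sample_shapes(truth$template, truth, 50, seed = 11)
  pl <- fit_pipeline(sh$meshes, noise_sd = 1, seed = 500)
  list(truth = truth, true_meshes = sh$meshes,
       true_coefficients = sh$coefficients,
       fitted = pl$fitted, reports = pl$reports)
})

# n = 200 cohort at 0.5 mm jitter: PCA coefficient-recovery property
fx_pca_cohort <- function() fixture("pca_cohort", function() {
  truth <- fx_truth()
  sh <- sample_shapes(truth$template, truth, 200, seed = 12)
  pl <- fit_pipeline(sh$meshes, noise_sd = 0.5, seed = 900)
  aligned <- align_cohort(pl$fitted)
  model <- fit_pca(aligned, n_retained = 10)
  co <- project_shape(model, do.call(rbind, lapply(aligned, flatten_mesh)))
  list(truth = truth, true_coefficients = sh$coefficients,
       aligned = aligned, model = model, coefficients = co)
})

# survival data with a sparse planted signal among 10 standardized modes
simulate_lasso_data <- function(n, seed, beta = NULL,
                                base_rate = 0.025, censor_rate = 0.08) {
  set.seed(seed)
  sds <- c(10, 8, 6, 5, 4, 3.5, 3, 2.5, 2, 1.5)
  X <- matrix(stats::rnorm(n * 10), n, 10) %*% diag(sds)
  if (is.null(beta)) beta <- rep(0, 10)
  lp <- as.vector(X %*% beta)
  t_evt <- stats::rexp(n, base_rate * exp(lp))
  t_cen <- stats::rexp(n, censor_rate)
  list(X = X, times = pmin(t_evt, t_cen, 16),
       events = as.integer(t_evt <= pmin(t_cen, 16)), sds = sds)
}
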