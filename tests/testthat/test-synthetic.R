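test_that("template construction honours its stated geometry", {
  tpl <- make_template(c(25, 25, 80), wall_thickness = 8, trunc_height = 70)
  expect_equal(mean_wall_thickness(tpl), 8, tolerance = 0.1 / 8)
  expect_equal(lv_length(tpl), 78, tolerance = 1e-6)

  # near-untruncated half-ellipsoid: analytic volume (2/3) pi a b c
  fine <- make_template(c(25, 25, 80), 8, 79.999, n_circ = 96, n_long = 64)
  expect_equal(cavity_volume(fine), (2 / 3) * pi * 25 * 25 * 80 / 1000,
               tolerance = 0.5 / 104.7)

  expect_error(make_template(c(25, 25, 80), 0, 70), "wall_thickness")
  expect_error(make_template(c(25, -25, 80), 8, 70), "semi_axes")
  expect_error(make_template(c(25, 25, 80), 8, 90), "trunc_height")
})

test_that("sample_shapes draws seeded coefficients with stated spread", {
  truth <- fx_truth()
  tpl <- truth$template

  # zero spread: every mesh equals the template
  t0 <- synthetic_truth(mode_sd = c(size = 0, sphericity = 0, arrhythmic = 0))
  sh0 <- sample_shapes(t0$template, t0, 3, seed = 1)
  expect_equal(sh0$meshes[[2]]$endo, t0$template$endo, tolerance = 1e-12)

  # law of large numbers on the coefficient SD
  t1 <- synthetic_truth(mode_names = "size", mode_sd = c(size = 3),
                        planted_log_hr = c(size = 0))
  sh1 <- sample_shapes(t1$template, t1, 1000, seed = 2)
  expect_equal(sd(sh1$coefficients[, 1]), 3, tolerance = 0.3 / 3)

  # independent draws on orthogonal modes
  sh2 <- sample_shapes(tpl, truth, 1000, seed = 3)
  expect_lt(abs(cor(sh2$coefficients[, 1], sh2$coefficients[, 2])), 0.1)

  # planted modes orthonormal
  g <- crossprod(truth$planted_modes)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)

  expect_error(sample_shapes(make_template(c(20, 20, 60), 6, 50,
                                           n_circ = 12, n_long = 8),
                             truth, 5),
               "dimension")
  expect_error(sample_shapes(tpl, truth, 1), "at least 2")
})

test_that("render_contours slices the mesh faithfully", {
  # cavity length 80, 10 mm slices -> floor(80/10) = 8 slices
  m <- make_template(c(30, 30, 90), 6, 80)
  st <- render_contours(m, 10, noise_sd = 0, seed = 1)
  expect_length(st$slices, 8L)

  # noiseless contour points lie on the faceted surface
  pts <- do.call(rbind, lapply(st$slices, function(s) cbind(s$endo, s$z)))
  co <- lvshape:::surface_correspondence(m$endo, m$n_circ, m$n_long, pts)
  expect_lt(max(co$resid, na.rm = TRUE), 0.05)

  # 1 mm jitter: mean distance to the noiseless contour ~ half-normal mean
  seg_dist <- function(p, poly) {
    a <- poly; b <- poly[c(2:nrow(poly), 1), ]
    ab <- b - a
    t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) /
      rowSums(ab^2)
    t <- pmin(pmax(t, 0), 1)
    q <- a + ab * t
    min(sqrt((q[, 1] - p[1])^2 + (q[, 2] - p[2])^2))
  }
  stn <- render_contours(m, 10, noise_sd = 1, seed = 4)
  d <- unlist(lapply(seq_along(stn$slices), function(i) {
    apply(stn$slices[[i]]$epi, 1, seg_dist, poly = st$slices[[i]]$epi)
  }))
  expect_gt(mean(d), 0.6)
  expect_lt(mean(d), 1.0)

  # landmark outside the epi contour of the most basal true slice
  basal <- st$slices[[st$landmark_slice]]
  expect_false(lvshape:::point_in_polygon(st$rv_landmark[1:2], basal$epi))

  expect_error(render_contours(m, 40, noise_sd = 0, thickness_range = c(7, 50)),
               "fewer than 3")
  expect_error(render_contours(m, 3), "outside admissible range")
  expect_error(render_contours(m, 10, noise_sd = -1), "noise_sd")
})

test_that("simulate_outcomes plants the stated proportional-hazards world", {
  truth <- fx_truth()
  K <- ncol(truth$planted_modes)

  # null effect: event times are an exponential sample
  t0 <- synthetic_truth(planted_log_hr = c(size = 0, sphericity = 0,
                                           arrhythmic = 0),
                        censor_rate = 0, horizon_years = 1e6)
  co <- matrix(rnorm(1000 * K), 1000, K)
  out0 <- simulate_outcomes(co, t0, seed = 5)
  expect_true(all(out0$event == 1))
  ks <- suppressWarnings(ks.test(out0$follow_up_years,
                                 "pexp", t0$baseline_hazard_rate))
  expect_gt(ks$p.value, 0.01)

  # proportional hazards: doubling a log(2)-coefficient doubles the rate
  t2 <- synthetic_truth(planted_log_hr = c(size = 0, sphericity = 0,
                                           arrhythmic = log(2)))
  co1 <- matrix(c(0, 0, 1), 1, 3); co2 <- matrix(c(0, 0, 2), 1, 3)
  lp1 <- simulate_outcomes(co1, t2, seed = 1)$linear_predictor
  lp2 <- simulate_outcomes(co2, t2, seed = 1)$linear_predictor
  expect_equal(exp(lp2 - lp1), 2, tolerance = 1e-12)

  # defaults: ~16% events at the study scale
  sh <- sample_shapes(truth$template, truth, 156, seed = 6)
  out <- simulate_outcomes(sh$coefficients, truth, seed = 6)
  expect_gte(sum(out$event), 15)
  expect_lte(sum(out$event), 35)
  expect_true(all(out$follow_up_years <= truth$horizon_years + 1e-12))

  expect_error(simulate_outcomes(co[, 1:2], truth, 1), "all planted modes")
  expect_error(synthetic_truth(baseline_hazard_rate = -1), "positive")
})

test_that("simulate_covariates applies MCAR missingness as stated", {
  cv <- simulate_covariates(1000, missing_frac = 0.15, seed = 7)
  fr <- mean(is.na(cv$smoker))
  expect_gt(fr, 0.12); expect_lt(fr, 0.18)
  expect_true(all(!is.na(cv$age)))

  cv0 <- simulate_covariates(200, missing_frac = 0, seed = 8)
  expect_false(anyNA(cv0))
  expect_error(simulate_covariates(10, missing_frac = 1), "missing_frac")

  # no confounding: covariates independent of the planted score
  truth <- fx_truth()
  sh <- sample_shapes(truth$template, truth, 1000, seed = 9)
  score <- sh$coefficients[, "arrhythmic"]
  cvi <- simulate_covariates(1000, seed = 10)
  expect_lt(abs(cor(score, cvi$age)), 0.1)
  expect_lt(abs(cor(score, cvi$lvef)), 0.1)
})

test_that("generate_cohort is reproducible and hazard-monotone", {
  a <- generate_cohort(n = 8, seed = 123, noise_sd = 0.5)
  b <- generate_cohort(n = 8, seed = 123, noise_sd = 0.5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$true_coefficients, b$true_coefficients)
  expect_identical(a$stacks[[3]]$slices, b$stacks[[3]]$slices)
  expect_identical(a$true_meshes[[5]]$endo, b$true_meshes[[5]]$endo)

  # event fraction responds monotonically to the baseline hazard
  truth <- fx_truth()
  sh <- sample_shapes(truth$template, truth, 400, seed = 20)
  evf <- vapply(c(0.005, 0.02, 0.08), function(r) {
    tt <- synthetic_truth(baseline_hazard_rate = r)
    mean(simulate_outcomes(sh$coefficients, tt, seed = 21)$event)
  }, numeric(1))
  expect_true(all(diff(evf) > 0))

  # device times respect follow-up
  expect_true(all(is.na(a$cohort$icd_time_years) |
                    a$cohort$icd_time_years <= a$cohort$follow_up_years))
})
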