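# All randomness in the generator flows from one integer master seed through
# named substreams, so each stage (anatomy, contours, outcomes, covariates,
# devices) is independently reproducible.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647)
}

default_template_params <- function() {
  # emulate the dilated-cardiomyopathy average geometry: cavity volume
  # 231.3 mL, apex-to-base length 85.46 mm, wall thickness 7.9 mm.
  thickness <- 7.9
  h <- 85.46 - thickness          # cavity height so epi-apex-to-base = 85.46
  cc <- 85                        # long semi-axis, base plane just below equator
  vol_mm3 <- 231.3 * 1000
  a <- sqrt(3 * vol_mm3 * cc^2 / (pi * h^2 * (3 * cc - h)))
  list(semi_axes = c(a, a, cc), wall_thickness = thickness, trunc_height = h)
}

# Smooth low-order deformation fields over the template lattice, then
# Gram-Schmidt orthonormalized in shape space.  The three defaults mirror the
# dominant directions seen in dilated-cardiomyopathy cohorts:
#   size        - uniform dilation about the centroid (EDV-like mode)
#   sphericity  - mid-cavity widening with long-axis shortening
#   arrhythmic  - basal widening (parabolic long-axis profile) with
#                 basal-lateral wall thinning (epicardium pulled inward)
make_planted_modes <- function(template,
                               which = c("size", "sphericity", "arrhythmic")) {
  x0 <- flatten_mesh(template)
  n_nodes <- n_surface_nodes(template$n_circ, template$n_long)
  pos <- rbind(template$endo, template$epi)
  ctr <- colMeans(pos)
  zr <- range(pos[, 3])
  zt <- (pos[, 3] - zr[1]) / diff(zr)        # 0 apex, 1 base
  ang <- atan2(pos[, 2] - ctr[2], pos[, 1] - ctr[1])
  is_epi <- c(rep(FALSE, n_nodes), rep(TRUE, n_nodes))
  radial <- cbind(pos[, 1] - ctr[1], pos[, 2] - ctr[2], 0)

  field <- function(name) {
    f <- switch(name,
      size = pos - matrix(ctr, nrow(pos), 3, byrow = TRUE),
      sphericity = {
        w <- sin(pi * pmin(pmax(zt, 0), 1))            # peaks mid-cavity
        radial * w - cbind(0, 0, pos[, 3] - mean(pos[, 3]))
      },
      arrhythmic = {
        w <- zt^2                                      # grows towards base
        # amplitude keeps the wall positive out to +/-3 SD exaggerations
        # while thinning the basal lateral wall by a few millimetres
        thin <- 0.35 * (1 + cos(ang - pi)) / 2 * zt^2  # basal lateral
        radial * w - radial * (thin * is_epi)
      },
      stop("unknown planted mode: ", name))
    as.vector(t(rbind(f[seq_len(n_nodes), ], f[-seq_len(n_nodes), ])))
  }
  raw <- vapply(which, field, numeric(length(x0)))
  # Gram-Schmidt
  for (k in seq_len(ncol(raw))) {
    v <- raw[, k]
    if (k > 1) {
      prev <- raw[, seq_len(k - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    raw[, k] <- v / sqrt(sum(v^2))
  }
  colnames(raw) <- which
  raw
}

#' Ground truth for a synthetic LV cohort
#'
#' Bundles everything the generator needs to produce a cohort with known
#' answers: the template geometry, mutually orthonormal planted deformation
#' modes with per-mode coefficient standard deviations, a planted
#' proportional-hazards effect per mode, exponential baseline event and
#' censoring rates, and an optional confounding map from covariates into the
#' shape-coefficient generator.
#'
#' Defaults state a cohort resembling the dilated-cardiomyopathy population
#' the package targets: average geometry 231.3 mL cavity / 85.46 mm length /
#' 7.9 mm wall, shape variation dominated by size and sphericity, a sparse
#' arrhythmic direction carrying log-HR 0.7 per coefficient SD, and event
#' and censor rates giving roughly 16\% events over a 16-year horizon with
#' median follow-up near 7.7 years.
#'
#' @param template_params list with `semi_axes`, `wall_thickness`,
#'   `trunc_height` (mm); see [make_template()].
#' @param mode_names planted deformation fields to construct.
#' @param mode_sd coefficient standard deviation per planted mode (mm).
#' @param planted_log_hr log hazard ratio per unit coefficient, per mode.
#' @param baseline_hazard_rate events/year at coefficient zero.
#' @param censor_rate independent exponential censoring rate (/year).
#' @param horizon_years administrative follow-up cap.
#' @param confounding_coeffs named list: covariate name -> numeric vector
#'   (length = number of planted modes) added to that patient's shape
#'   coefficients per SD of the covariate.  Empty list = no confounding.
#' @param n_circ,n_long lattice resolution of the generated meshes.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(template_params = default_template_params(),
                            mode_names = c("size", "sphericity", "arrhythmic"),
                            mode_sd = c(size = 120, sphericity = 60,
                                        arrhythmic = 25),
                            planted_log_hr = c(size = 0, sphericity = 0,
                                               arrhythmic = 0.7 / 25),
                            baseline_hazard_rate = 0.015,
                            censor_rate = 0.071,
                            horizon_years = 16,
                            confounding_coeffs = list(),
                            n_circ = 24L, n_long = 16L) {
  if (any(mode_sd < 0)) stop("mode_sd must be non-negative")
  if (baseline_hazard_rate <= 0) stop("baseline_hazard_rate must be positive")
  if (censor_rate < 0) stop("censor_rate must be non-negative")
  template <- make_template(template_params$semi_axes,
                            template_params$wall_thickness,
                            template_params$trunc_height,
                            n_circ = n_circ, n_long = n_long)
  modes <- make_planted_modes(template, mode_names)
  K <- ncol(modes)
  stopifnot(length(mode_sd) == K, length(planted_log_hr) == K)
  g <- crossprod(modes) - diag(K)
  if (max(abs(g)) > 1e-8) stop("planted modes are not orthonormal")
  structure(
    list(template_params = template_params, template = template,
         planted_modes = modes, mode_sd = mode_sd,
         planted_log_hr = planted_log_hr,
         baseline_hazard_rate = baseline_hazard_rate,
         censor_rate = censor_rate, horizon_years = horizon_years,
         confounding_coeffs = confounding_coeffs),
    class = "synthetic_truth"
  )
}

#' Sample meshes from the planted shape model
#'
#' Each mesh is the template shape vector plus a random combination of the
#' planted modes, `x = x_template + sum_k c_k m_k`, with
#' `c_k ~ N(0, mode_sd_k^2)`.  The drawn coefficients are returned so
#' downstream recovery (PCA, Cox-Lasso) can be checked against truth.
#'
#' @param template `lv_mesh` matching the planted-mode dimension.
#' @param truth a [synthetic_truth()].
#' @param n number of meshes (>= 2).
#' @param seed integer seed.
#' @param coeff_shift optional n x K matrix added to the drawn coefficients
#'   (used to inject covariate confounding).
#' @return list with `meshes` (list of `lv_mesh`) and `coefficients`
#'   (n x K matrix, the realized coefficients including any shift).
#' @export
sample_shapes <- function(template, truth, n, seed = 1L, coeff_shift = NULL) {
  if (n < 2) stop("n must be at least 2")
  modes <- truth$planted_modes
  x0 <- flatten_mesh(template)
  if (nrow(modes) != length(x0)) {
    stop("planted mode dimension does not match template")
  }
  K <- ncol(modes)
  set.seed(seed)
  co <- matrix(stats::rnorm(n * K), n, K) %*% diag(truth$mode_sd, K)
  if (!is.null(coeff_shift)) {
    stopifnot(nrow(coeff_shift) == n, ncol(coeff_shift) == K)
    co <- co + coeff_shift
  }
  colnames(co) <- colnames(modes)
  meshes <- lapply(seq_len(n), function(i) {
    unflatten_mesh(x0 + as.vector(modes %*% co[i, ]),
                   template$n_circ, template$n_long,
                   rv_direction = template$rv_direction)
  })
  list(meshes = meshes, coefficients = co)
}

# intersect one lattice column (apex node + ring nodes, apex to base) with
# the plane z = z0; linear interpolation along the column polyline.  Points
# produced this way lie exactly on the faceted surface (column segments are
# triangulation edges).
column_plane_point <- function(colxyz, z0) {
  z <- colxyz[, 3]
  for (s in seq_len(nrow(colxyz) - 1L)) {
    z1 <- z[s]; z2 <- z[s + 1L]
    if ((z1 <= z0 && z0 <= z2) || (z2 <= z0 && z0 <= z1)) {
      t <- if (z2 == z1) 0 else (z0 - z1) / (z2 - z1)
      return(colxyz[s, 1:2] + t * (colxyz[s + 1L, 1:2] - colxyz[s, 1:2]))
    }
  }
  c(NA_real_, NA_real_)
}

surface_columns <- function(nodes, n_circ, n_long) {
  lapply(seq_len(n_circ), function(i) {
    rows <- 1L + (seq_len(n_long) - 1L) * n_circ + i
    rbind(nodes[1L, ], nodes[rows, ])
  })
}

#' Render a short-axis contour stack from a mesh
#'
#' Emulates segmented CMR: the mesh is cut by equally spaced short-axis
#' planes, one epicardial and one endocardial polygon per slice, with
#' optional isotropic in-plane Gaussian jitter on every contour point.  The
#' number of slices is `floor(cavity_length / slice_thickness)`, placed from
#' the base downward.  A right-ventricular landmark is placed at the mesh's
#' `rv_direction` angle, outside the epicardial contour of the most basal
#' (true) slice.  `n_supra_basal` additional slices above the base (slightly
#' dilated copies of the basal contours) emulate valve-plane images that the
#' basal truncation step must remove; the stack records which slice carries
#' the landmark so generators' bookkeeping can be checked.
#'
#' `in_plane_res` is carried as acquisition metadata only (the contours are
#' geometric, not rasterized).
#'
#' @param mesh source `lv_mesh`.
#' @param slice_thickness slice spacing, mm (typical short-axis protocols:
#'   7-10.5 mm).
#' @param in_plane_res in-plane resolution metadata, mm (typical 1.3-2.2).
#' @param noise_sd in-plane jitter SD per contour point, mm.
#' @param seed integer seed for the jitter.
#' @param patient_id stored in the stack.
#' @param n_supra_basal number of supra-basal (valve-plane) slices appended.
#' @param thickness_range admissible `slice_thickness` range.
#' @return a `contour_stack` (see [contour_stack()]).
#' @export
render_contours <- function(mesh, slice_thickness, in_plane_res = 1.8,
                            noise_sd = 0, seed = 1L, patient_id = "synthetic",
                            n_supra_basal = 0L,
                            thickness_range = c(7, 10.5)) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (slice_thickness < thickness_range[1] ||
      slice_thickness > thickness_range[2]) {
    stop(sprintf("slice_thickness %.2f outside admissible range [%.1f, %.1f]",
                 slice_thickness, thickness_range[1], thickness_range[2]))
  }
  zb <- mesh_base_z(mesh)
  za <- endo_apex_z(mesh)
  cav_len <- zb - za
  n_slices <- floor(cav_len / slice_thickness)
  if (n_slices < 3) {
    stop("slice thickness too large for mesh length: fewer than 3 slices")
  }
  zpos <- zb - (n_slices:1 - 0.5) * slice_thickness # ascending, apex to base
  cols_endo <- surface_columns(mesh$endo, mesh$n_circ, mesh$n_long)
  cols_epi <- surface_columns(mesh$epi, mesh$n_circ, mesh$n_long)
  set.seed(seed)
  cut_at <- function(cols, z0) {
    p <- t(vapply(cols, column_plane_point, numeric(2), z0 = z0))
    p[stats::complete.cases(p), , drop = FALSE]
  }
  # iid jitter can fold a small (apical) polygon onto itself, which a real
  # segmentation never does; redraw such slices (seeded, bounded attempts)
  jitter_simple <- function(poly) {
    if (noise_sd == 0) return(poly)
    for (try in 1:25) {
      cand <- poly + matrix(stats::rnorm(length(poly), 0, noise_sd), ncol = 2)
      if (polygon_simple(cand)) return(cand)
    }
    poly
  }
  slices <- lapply(zpos, function(z0) {
    list(z = z0, epi = jitter_simple(cut_at(cols_epi, z0)),
         endo = jitter_simple(cut_at(cols_endo, z0)))
  })
  basal <- slices[[n_slices]]
  if (n_supra_basal > 0) {
    for (k in seq_len(n_supra_basal)) {
      dil <- function(p) {
        ctr <- colMeans(p)
        sweep(sweep(p, 2, ctr) * 1.05^k, 2, -ctr)
      }
      slices[[n_slices + k]] <- list(z = basal$z + k * slice_thickness,
                                     epi = dil(basal$epi),
                                     endo = dil(basal$endo))
    }
  }
  rv_ang <- if (is.na(mesh$rv_direction)) 0 else mesh$rv_direction
  ctr <- colMeans(basal$epi)
  rel <- sweep(basal$epi, 2, ctr)
  ang <- atan2(rel[, 2], rel[, 1])
  nearest <- which.min(abs(((ang - rv_ang + pi) %% (2 * pi)) - pi))
  lm_xy <- ctr + 1.6 * rel[nearest, ]
  contour_stack(patient_id = patient_id, slices = slices,
                slice_thickness = slice_thickness,
                in_plane_res = in_plane_res,
                rv_landmark = c(lm_xy, basal$z),
                landmark_slice = n_slices)
}

#' Simulate arrhythmic-event outcomes under planted proportional hazards
#'
#' Event times are exponential with patient-specific rate
#' `baseline_hazard_rate * exp(sum_k log_hr_k c_ik)`; censoring is an
#' independent exponential at `censor_rate`, and follow-up is capped at the
#' administrative horizon.  Follow-up equals the event time whenever the
#' event indicator is 1.
#'
#' @param coefficients n x K matrix of planted-mode coefficients.
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @return data.frame with `follow_up_years`, `event`, and the latent
#'   `linear_predictor`.
#' @export
simulate_outcomes <- function(coefficients, truth, seed = 1L) {
  K <- ncol(truth$planted_modes)
  if (ncol(coefficients) != K) {
    stop("coefficients must include all planted modes")
  }
  lp <- as.vector(coefficients %*% truth$planted_log_hr)
  rate <- truth$baseline_hazard_rate * exp(lp)
  if (any(!is.finite(rate)) || any(rate <= 0)) stop("non-positive hazard rate")
  set.seed(seed)
  n <- nrow(coefficients)
  t_evt <- stats::rexp(n, rate)
  t_cen <- if (truth$censor_rate > 0) stats::rexp(n, truth$censor_rate)
           else rep(Inf, n)
  fu <- pmin(t_evt, t_cen, truth$horizon_years)
  data.frame(follow_up_years = fu,
             event = as.integer(t_evt <= pmin(t_cen, truth$horizon_years)),
             linear_predictor = lp)
}

#' Simulate baseline covariates
#'
#' Produces a mix of continuous and binary covariates with marginals loosely
#' matching a dilated-cardiomyopathy cohort (age ~58y, 82\% male, LVEF ~38\%,
#' ...).  Missingness is applied completely at random to the designated
#' columns (`smoker`, `afib`, `mitral_regurg`), emulating the variables that
#' carry missing entries in registry data.
#'
#' @param n patients.
#' @param missing_frac fraction missing in the designated columns, in [0, 1).
#' @param seed integer seed.
#' @return data.frame of covariates.
#' @export
simulate_covariates <- function(n, missing_frac = 0, seed = 1L) {
  if (missing_frac < 0 || missing_frac >= 1) {
    stop("missing_frac must be in [0, 1)")
  }
  set.seed(seed)
  df <- data.frame(
    age = stats::rnorm(n, 58, 13),
    male = stats::rbinom(n, 1, 0.82),
    bsa = stats::rnorm(n, 2.0, 0.22),
    heart_rate = stats::rnorm(n, 71, 13),
    lvef = pmax(stats::rnorm(n, 38, 11), 10),
    lv_mass_index = stats::rnorm(n, 96, 25),
    lge_volume = stats::rgamma(n, shape = 2, scale = 4),
    alcohol_excess = stats::rbinom(n, 1, 0.16),
    nyha34 = stats::rbinom(n, 1, 0.17),
    beta_blocker = stats::rbinom(n, 1, 0.82),
    smoker = stats::rbinom(n, 1, 0.10),
    afib = stats::rbinom(n, 1, 0.32),
    mitral_regurg = stats::rbinom(n, 1, 0.57)
  )
  if (missing_frac > 0) {
    for (col in c("smoker", "afib", "mitral_regurg")) {
      df[[col]][stats::runif(n) < missing_frac] <- NA
    }
  }
  df
}

confounding_shift <- function(covariates, confounding_coeffs, K) {
  shift <- matrix(0, nrow(covariates), K)
  for (nm in names(confounding_coeffs)) {
    v <- covariates[[nm]]
    if (is.null(v)) stop("confounding covariate not present: ", nm)
    z <- as.numeric(scale(as.numeric(v)))
    z[is.na(z)] <- 0
    gamma <- confounding_coeffs[[nm]]
    if (length(gamma) == 1L) gamma <- c(rep(0, K - 1L), gamma)
    stopifnot(length(gamma) == K)
    shift <- shift + outer(z, gamma)
  }
  shift
}

#' Generate a full synthetic cohort
#'
#' End-to-end generator: covariates, planted-mode coefficients (optionally
#' confounded by covariates), meshes, rendered contour stacks with
#' per-patient acquisition geometry, exponential outcomes under the planted
#' proportional-hazards effect, and device (ICD/CRT) implant times.
#' Bit-reproducible for a fixed master seed; each stage draws from its own
#' named substream.
#'
#' @param n cohort size (default 156, the scale of the motivating study).
#' @param truth a [synthetic_truth()].
#' @param seed master integer seed.
#' @param noise_sd contour jitter SD, mm.
#' @param missing_frac covariate missingness fraction.
#' @param n_supra_basal supra-basal slices per stack.
#' @param icd_frac,crt_frac_given_icd device implantation rates.
#' @return list with `stacks`, `cohort` (covariates + follow-up + event +
#'   device times), `true_meshes`, `true_coefficients`, `truth`, `template`.
#' @export
generate_cohort <- function(n = 156, truth = synthetic_truth(), seed = 1L,
                            noise_sd = 1, missing_frac = 0,
                            n_supra_basal = 1L,
                            icd_frac = 0.52, crt_frac_given_icd = 0.55) {
  covs <- simulate_covariates(n, missing_frac,
                              seed = substream_seed(seed, "covariates"))
  K <- ncol(truth$planted_modes)
  shift <- confounding_shift(covs, truth$confounding_coeffs, K)
  shift <- shift %*% diag(truth$mode_sd, K)  # confounding in SD units
  shapes <- sample_shapes(truth$template, truth, n,
                          seed = substream_seed(seed, "anatomy"),
                          coeff_shift = shift)
  set.seed(substream_seed(seed, "acquisition"))
  slice_th <- stats::runif(n, 7, 10.5)
  res <- stats::runif(n, 1.3, 2.2)
  stacks <- lapply(seq_len(n), function(i) {
    render_contours(shapes$meshes[[i]], slice_thickness = slice_th[i],
                    in_plane_res = res[i], noise_sd = noise_sd,
                    seed = substream_seed(seed, paste0("contours", i)),
                    patient_id = sprintf("SYN%04d", i),
                    n_supra_basal = n_supra_basal)
  })
  out <- simulate_outcomes(shapes$coefficients, truth,
                           seed = substream_seed(seed, "outcomes"))
  set.seed(substream_seed(seed, "devices"))
  has_icd <- stats::rbinom(n, 1, icd_frac) == 1
  icd_time <- ifelse(has_icd, stats::runif(n) * out$follow_up_years, NA)
  has_crt <- has_icd & stats::rbinom(n, 1, crt_frac_given_icd) == 1
  crt_time <- ifelse(has_crt,
                     icd_time + stats::runif(n) *
                       pmax(out$follow_up_years - icd_time, 0), NA)
  cohort <- cbind(data.frame(patient_id = sprintf("SYN%04d", seq_len(n))),
                  covs, out[c("follow_up_years", "event")],
                  data.frame(icd_time_years = icd_time,
                             crt_time_years = crt_time))
  list(stacks = stacks, cohort = cohort,
       true_meshes = shapes$meshes, true_coefficients = shapes$coefficients,
       truth = truth, template = truth$template,
       linear_predictor = out$linear_predictor)
}
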