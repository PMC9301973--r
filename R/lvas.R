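# --- Cox partial likelihood (Efron ties), gradient and Hessian -------------

# the sort order and tie-block structure depend only on the data, so they
# are computed once per dataset and reused across a whole lasso path
cox_prep <- function(X, times, events) {
  X <- as.matrix(X)
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (sum(events) == 0) stop("no events: partial likelihood undefined")
  ord <- order(times, decreasing = TRUE)
  tt <- times[ord]; ev <- events[ord]
  n <- length(tt)
  blocks <- list(); i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1L] == tt[i]) j <- j + 1L
    D <- (i:j)[ev[i:j] == 1]
    if (length(D) > 0) blocks[[length(blocks) + 1L]] <- list(end = j, D = D)
    i <- j + 1L
  }
  # untied events (the common case) are handled vectorized
  d1 <- vapply(blocks, function(b) length(b$D) == 1L, logical(1))
  list(Xo = X[ord, , drop = FALSE], blocks = blocks[!d1],
       end1 = vapply(blocks[d1], `[[`, integer(1), "end"),
       D1 = vapply(blocks[d1], `[[`, integer(1), "D"),
       p = ncol(X), n = n)
}

# loglik only (fast path used by the objective and the CV curve); the
# max(eta) stabilization shift cancels between event terms and denominators
cox_pll_ll <- function(beta, prep) {
  eta <- as.vector(prep$Xo %*% beta)
  eta <- eta - max(eta)
  wo <- exp(eta)
  cw <- cumsum(wo)
  ll <- if (length(prep$D1)) sum(eta[prep$D1]) - sum(log(cw[prep$end1])) else 0
  for (b in prep$blocks) {
    d <- length(b$D)
    sr <- cw[b$end]
    sd_ <- sum(wo[b$D])
    ll <- ll + sum(eta[b$D]) -
      sum(log(sr - (seq_len(d) - 1L) / d * sd_))
  }
  ll
}

cox_pll_deriv <- function(beta, prep) {
  p <- prep$p
  Xo <- prep$Xo
  eta <- as.vector(Xo %*% beta)
  eta <- eta - max(eta)
  wo <- exp(eta)
  cw <- cumsum(wo)
  cwx <- apply(Xo * wo, 2, cumsum)
  if (p == 1L) cwx <- matrix(cwx, ncol = 1L)
  xx <- Xo[, rep(seq_len(p), times = p), drop = FALSE] *
    Xo[, rep(seq_len(p), each = p), drop = FALSE] * wo
  cwxx <- apply(xx, 2, cumsum)
  if (ncol(xx) == 1L) cwxx <- matrix(cwxx, ncol = 1L)
  ll <- 0; grad <- numeric(p); hess <- matrix(0, p, p)
  if (length(prep$D1)) {
    sr <- cw[prep$end1]
    GX <- cwx[prep$end1, , drop = FALSE] / sr
    ll <- sum(eta[prep$D1]) - sum(log(sr))
    grad <- colSums(Xo[prep$D1, , drop = FALSE]) - colSums(GX)
    hess <- matrix(colSums(cwxx[prep$end1, , drop = FALSE] / sr), p, p) -
      crossprod(GX)
  }
  for (b in prep$blocks) {
    D <- b$D; d <- length(D)
    sr <- cw[b$end]; srx <- cwx[b$end, ]; srxx <- matrix(cwxx[b$end, ], p, p)
    sd_ <- sum(wo[D])
    sdx <- colSums(Xo[D, , drop = FALSE] * wo[D])
    sdxx <- matrix(colSums(xx[D, , drop = FALSE]), p, p)
    ll <- ll + sum(eta[D])
    grad <- grad + colSums(Xo[D, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      den <- sr - f * sd_
      gx <- (srx - f * sdx) / den
      ll <- ll - log(den)
      grad <- grad - gx
      hess <- hess + (srxx - f * sdxx) / den - tcrossprod(gx)
    }
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

cox_pll_parts <- function(beta, X, times, events) {
  cox_pll_deriv(as.numeric(beta), cox_prep(X, times, events))
}

#' Cox partial log-likelihood with Efron tie handling
#'
#' Exact partial log-likelihood of a Cox proportional-hazards model at a
#' given coefficient vector, with the Efron correction for tied event
#' times (identical to Breslow when there are no ties).  The analytic
#' gradient and (negative-curvature) Hessian are available for the
#' coordinate-descent lasso solver and for KKT verification.
#'
#' @param beta coefficient vector (length = columns of `x`).
#' @param x N x p covariate matrix.
#' @param times follow-up times (> 0).
#' @param events 0/1 event indicators (at least one event).
#' @param derivatives if TRUE return a list with `loglik`, `gradient`,
#'   `hessian`; otherwise the log-likelihood value.
#' @export
cox_partial_loglik <- function(beta, x, times, events, derivatives = FALSE) {
  parts <- cox_pll_parts(beta, x, times, events)
  if (derivatives) parts else parts$loglik
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# one lambda: cyclic coordinate descent on successive quadratic
# approximations of the partial likelihood, with a step-halving safeguard
cox_lasso_fit1 <- function(prep, lambda, beta0, tol = 1e-8, max_outer = 100L) {
  p <- prep$p
  objective <- function(b) -cox_pll_ll(b, prep) + lambda * sum(abs(b))
  beta <- beta0
  obj <- objective(beta)
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    parts <- cox_pll_deriv(beta, prep)
    g <- parts$gradient; H <- parts$hessian
    diag(H) <- diag(H) + 1e-10
    bq <- beta
    for (sweep_i in 1:200) {
      delta <- 0
      for (j in seq_len(p)) {
        z <- g[j] - sum(H[j, ] * (bq - beta)) + H[j, j] * bq[j]
        new <- soft_threshold(z, lambda) / H[j, j]
        delta <- max(delta, abs(new - bq[j]))
        bq[j] <- new
      }
      if (delta < tol) break
    }
    step <- bq - beta
    new_obj <- objective(bq)
    halvings <- 0L
    while (new_obj > obj + 1e-12 && halvings < 30L) {
      step <- step / 2
      bq <- beta + step
      new_obj <- objective(bq)
      halvings <- halvings + 1L
    }
    moved <- max(abs(bq - beta))
    beta <- bq; obj <- new_obj
    if (moved < tol * 10) { converged <- TRUE; break }
  }
  # coordinates at the KKT boundary can pick up float-epsilon residue;
  # exact zeros keep the support (and the CV selection) clean
  beta[abs(beta) < 1e-10] <- 0
  list(beta = beta, converged = converged)
}

#' Cox-Lasso regularization path
#'
#' L1-penalized Cox regression, maximizing
#' `partial log-likelihood - lambda * sum(|beta_j|)` by cyclic coordinate
#' descent on local quadratic approximations with warm starts along a
#' decreasing log-spaced lambda grid.  Covariates are standardized to unit
#' variance inside the fit (lasso penalties are scale-sensitive); weights
#' are reported on both the standardized and the raw coefficient scale.
#' `lambda_max`, computed from the null-model gradient, is the smallest
#' penalty at which the whole path is exactly zero.  KKT optimality
#' (`|g_j| <= lambda` for inactive, `g_j = lambda sign(beta_j)` for active
#' coordinates) is verified at every path point.
#'
#' @param x N x p matrix of mode coefficients (or other covariates).
#' @param times,events survival outcome.
#' @param lambda optional penalty grid (decreasing); by default 100
#'   log-spaced values from `lambda_max` down to `1e-3 * lambda_max`.
#' @param nlambda,lambda_min_ratio grid controls when `lambda` is NULL.
#' @param standardize standardize columns inside the fit (default TRUE).
#' @param kkt_tol tolerance for the KKT verification.
#' @return object of class `cox_lasso_path`: `lambda`, `beta` (raw scale,
#'   p x nlambda), `beta_std`, `center`, `scale`, `converged`, `kkt_ok`.
#' @export
cox_lasso_path <- function(x, times, events, lambda = NULL, nlambda = 100L,
                           lambda_min_ratio = 1e-3, standardize = TRUE,
                           kkt_tol = 1e-6) {
  X <- as.matrix(x)
  p <- ncol(X)
  center <- colMeans(X)
  scale <- if (standardize) apply(X, 2, stats::sd) else rep(1, p)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  prep <- cox_prep(Xs, times, events)
  g0 <- cox_pll_deriv(numeric(p), prep)$gradient
  lambda_max <- max(abs(g0))
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  nl <- length(lambda)
  beta_std <- matrix(0, p, nl)
  converged <- kkt_ok <- logical(nl)
  beta <- numeric(p)
  for (k in seq_len(nl)) {
    fit <- cox_lasso_fit1(prep, lambda[k], beta)
    beta <- fit$beta
    beta_std[, k] <- beta
    converged[k] <- fit$converged
    if (!fit$converged) {
      warning(sprintf("coordinate descent did not converge at lambda=%.4g",
                      lambda[k]))
    }
    g <- cox_pll_deriv(beta, prep)$gradient
    act <- abs(beta) > 0
    kkt_ok[k] <- all(abs(g[!act]) <= lambda[k] + kkt_tol) &&
      (!any(act) || all(abs(g[act] - lambda[k] * sign(beta[act])) <= kkt_tol))
  }
  structure(list(lambda = lambda, lambda_max = lambda_max,
                 beta = beta_std / scale, beta_std = beta_std,
                 center = center, scale = scale,
                 converged = converged, kkt_ok = kkt_ok),
            class = "cox_lasso_path")
}

# stratified fold labels: events and censored spread evenly
stratified_folds <- function(events, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(events))
  for (grp in list(which(events == 1), which(events == 0))) {
    fold[sample(grp)] <- rep_len(seq_len(n_folds), length(grp))
  }
  fold
}

#' Select the lasso penalty by cross-validated partial likelihood
#'
#' Verweij-van Houwelingen cross-validated log partial likelihood:
#' `CV(lambda) = sum_k [ ll_full(beta_(-k)) - ll_(-k)(beta_(-k)) ]`, where
#' `beta_(-k)` is the path fitted without fold k (same lambda grid
#' throughout, warm starts, fold assignment stratified by event status).
#' The selected penalty maximizes the curve.
#'
#' @param x,times,events as in [cox_lasso_path()].
#' @param n_folds folds (>= 3, default 10).
#' @param seed fold-assignment seed.
#' @param nlambda,lambda_min_ratio,standardize passed to the path.
#' @param folds optional explicit fold labels (1..n_folds); the CV curve
#'   depends only on the partition, not on the labelling.
#' @return list: `lambda_selected`, `cv_curve` (data.frame lambda/cvl),
#'   `path` (full-data `cox_lasso_path`), `folds`, `n_folds`, `seed`.
#' @export
cv_select <- function(x, times, events, n_folds = 10L, seed = 1L,
                      nlambda = 100L, lambda_min_ratio = 1e-3,
                      standardize = TRUE, folds = NULL) {
  if (n_folds < 3) stop("need at least 3 folds")
  X <- as.matrix(x)
  full <- cox_lasso_path(X, times, events, nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio,
                         standardize = standardize)
  lambda <- full$lambda
  fold <- folds
  if (is.null(fold)) {
    for (attempt in 0:4) {
      fold <- stratified_folds(events, n_folds, seed + attempt)
      ok <- all(vapply(seq_len(n_folds), function(k) {
        sum(events[fold != k]) > 0 && sum(events[fold == k]) > 0
      }, logical(1)))
      if (ok) break
      fold <- NULL
    }
  } else {
    n_folds <- length(unique(fold))
    if (any(vapply(seq_len(n_folds), function(k) {
      sum(events[fold != k]) == 0 || sum(events[fold == k]) == 0
    }, logical(1)))) {
      stop("supplied folds leave a fold without events")
    }
  }
  if (is.null(fold)) {
    stop("could not build folds with events in every fold after 5 attempts")
  }
  cvl <- numeric(length(lambda))
  prep_full <- cox_prep(X, times, events)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    pk <- cox_lasso_path(X[tr, , drop = FALSE], times[tr], events[tr],
                         lambda = lambda, standardize = standardize)
    prep_tr <- cox_prep(X[tr, , drop = FALSE], times[tr], events[tr])
    for (i in seq_along(lambda)) {
      b <- pk$beta[, i]
      cvl[i] <- cvl[i] + (cox_pll_ll(b, prep_full) - cox_pll_ll(b, prep_tr))
    }
  }
  best <- which.max(cvl)
  list(lambda_selected = lambda[best],
       cv_curve = data.frame(lambda = lambda, cvl = cvl),
       path = full, folds = fold, n_folds = n_folds, seed = seed)
}

#' Learn the LV arrhythmic shape (LVAS) score
#'
#' Runs the Cox-Lasso with cross-validated-likelihood penalty selection on
#' the retained PCA mode coefficients, freezes the sparse weights, and sets
#' up the max-min normalization: `raw_i = sum_j beta_j c_ij`, normalized to
#' (0-1) with the training minimum and maximum, higher score = higher
#' hazard (the Cox orientation).  Training quartile cutpoints of the
#' normalized score are stored for per-quartile hazard modelling.
#'
#' @param shape_model the fitted `shape_model` (for bookkeeping; its
#'   `n_retained` must match `coefficients`).
#' @param coefficients N x n_retained training mode coefficients.
#' @param times,events survival outcome.
#' @param n_folds,seed,nlambda,lambda_min_ratio CV controls.
#' @return object of class `lvas_model`.
#' @export
build_lvas <- function(shape_model, coefficients, times, events,
                       n_folds = 10L, seed = 1L, nlambda = 100L,
                       lambda_min_ratio = 1e-3) {
  X <- as.matrix(coefficients)
  if (!is.null(shape_model) && ncol(X) != shape_model$n_retained) {
    stop("coefficient columns must match the shape model's retained modes")
  }
  cv <- cv_select(X, times, events, n_folds = n_folds, seed = seed,
                  nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
  beta <- cv$path$beta[, match(cv$lambda_selected, cv$path$lambda)]
  if (all(beta == 0)) {
    stop("no prognostic shape signal at selected lambda (all weights zero)")
  }
  raw <- as.vector(X %*% beta)
  rmin <- min(raw); rmax <- max(raw)
  normalized <- (raw - rmin) / (rmax - rmin)
  structure(
    list(weights = beta,
         selected_mode_indices = which(beta != 0),
         lambda_selected = cv$lambda_selected,
         cv_curve = cv$cv_curve,
         raw_score_min = rmin, raw_score_max = rmax,
         quartile_cutpoints = unname(stats::quantile(normalized,
                                                     c(0.25, 0.5, 0.75)))),
    class = "lvas_model")
}

#' @export
print.lvas_model <- function(x, ...) {
  cat(sprintf("lvas_model: modes {%s}, weights (%s), lambda=%.4g\n",
              paste(x$selected_mode_indices, collapse = ", "),
              paste(sprintf("%.4g", x$weights[x$selected_mode_indices]),
                    collapse = ", "),
              x$lambda_selected))
  invisible(x)
}

#' Normalized LVAS scores from mode coefficients
#'
#' @param lvas_model an `lvas_model`.
#' @param coefficients vector (one patient) or matrix of mode coefficients.
#' @param clip clip out-of-training-range raw scores into [0, 1] with a
#'   warning (the behaviour for new patients).
#' @return numeric normalized score(s).
#' @export
lvas_scores <- function(lvas_model, coefficients, clip = TRUE) {
  co <- if (is.matrix(coefficients)) coefficients else
    matrix(coefficients, nrow = 1)
  raw <- as.vector(co %*% lvas_model$weights)
  s <- (raw - lvas_model$raw_score_min) /
    (lvas_model$raw_score_max - lvas_model$raw_score_min)
  if (clip && any(s < 0 | s > 1)) {
    warning("raw score outside training bounds; clipped to [0, 1]")
    s <- pmin(pmax(s, 0), 1)
  }
  s
}

#' Score a single patient mesh
#'
#' Aligns the mesh (centre of mass to origin, RV direction to +x), projects
#' it onto the shape model, applies the frozen sparse weights and the
#' stored training max-min normalization.  Rigid repositioning of the input
#' therefore does not change the score.
#'
#' @param lvas_model an `lvas_model`.
#' @param shape_model the `shape_model` used in training.
#' @param mesh an `lv_mesh` with an RV landmark direction.
#' @return normalized LVAS in [0, 1].
#' @export
score_patient <- function(lvas_model, shape_model, mesh) {
  if (!inherits(mesh, "lv_mesh")) stop("mesh must be an lv_mesh")
  if (!is.null(shape_model$n_circ) &&
      (mesh$n_circ != shape_model$n_circ || mesh$n_long != shape_model$n_long)) {
    stop("mesh topology does not match the shape model")
  }
  aligned <- if (!is.na(mesh$rv_direction)) align_mesh(mesh) else mesh
  co <- project_shape(shape_model, aligned)
  lvas_scores(lvas_model, co)
}

#' Quartile coding of LVAS scores
#'
#' Integer quartile index 0-3 by the training cutpoints, ties assigned to
#' the lower quartile.  Entered as a continuous covariate in Cox models,
#' this gives the "hazard ratio per quartile" reporting convention.
#'
#' @param scores normalized scores.
#' @param cutpoints three training quartile cutpoints.
#' @return integer vector in 0..3.
#' @export
quartile_code <- function(scores, cutpoints) {
  findInterval(scores, sort(cutpoints), left.open = TRUE)
}
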