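#' Build the PCA statistical shape model
#'
#' Eigendecomposition of the sample covariance of aligned shape vectors.
#' When the vector dimension exceeds the cohort size the decomposition is
#' computed through the N x N Gram matrix (the usual trick for
#' high-dimensional point-distribution models), which is exact for the
#' non-null spectrum.  Modes are orthonormal, ordered by decreasing
#' variance, and sign-fixed: each mode is flipped so that moving along it
#' increases cavity volume (falling back to "largest-magnitude component
#' positive" when the volume change is negligible or no lattice topology is
#' attached), so serialized models are comparable across runs.
#'
#' @param shapes either a numeric N x D matrix of shape vectors or a list of
#'   aligned `lv_mesh` objects sharing one topology.
#' @param n_retained number of modes kept for projection/reconstruction
#'   (default 10).
#' @param n_circ,n_long lattice topology (taken from the meshes when a list
#'   is given); needed for mesh reconstruction and the volume sign rule.
#' @return object of class `shape_model`: `mean`, `modes` (D x K, all
#'   positive-variance modes), `eigenvalues` (mm^2, full spectrum),
#'   `n_retained`, `n_train`, `n_circ`, `n_long`.
#' @export
fit_pca <- function(shapes, n_retained = 10L, n_circ = NULL, n_long = NULL) {
  if (is.list(shapes) && inherits(shapes[[1]], "lv_mesh")) {
    n_circ <- shapes[[1]]$n_circ; n_long <- shapes[[1]]$n_long
    shapes <- do.call(rbind, lapply(shapes, flatten_mesh))
  }
  X <- as.matrix(shapes)
  N <- nrow(X); D <- ncol(X)
  if (N < 3) stop("need at least 3 shapes")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (D > N) {
    G <- tcrossprod(Xc)                      # N x N
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    if (!any(pos)) stop("rank-zero shape matrix: all shapes identical")
    U <- eg$vectors[, pos, drop = FALSE]
    lam_g <- eg$values[pos]
    modes <- crossprod(Xc, U) / rep(sqrt(lam_g), each = D)
    eigenvalues <- lam_g / (N - 1)
  } else {
    S <- crossprod(Xc) / (N - 1)
    eg <- eigen(S, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    if (!any(pos)) stop("rank-zero shape matrix: all shapes identical")
    modes <- eg$vectors[, pos, drop = FALSE]
    eigenvalues <- eg$values[pos]
  }
  model <- structure(
    list(mean = mu, modes = modes, eigenvalues = eigenvalues,
         n_retained = min(as.integer(n_retained), ncol(modes)),
         n_train = N, n_circ = n_circ, n_long = n_long),
    class = "shape_model")
  fix_mode_signs(model)
}

fix_mode_signs <- function(model) {
  has_topo <- !is.null(model$n_circ) && !is.null(model$n_long)
  base_vol <- if (has_topo) {
    cavity_volume(unflatten_mesh(model$mean, model$n_circ, model$n_long))
  } else NA_real_
  for (k in seq_len(ncol(model$modes))) {
    m <- model$modes[, k]
    flip <- FALSE
    decided <- FALSE
    if (has_topo) {
      s <- sqrt(model$eigenvalues[k])
      vp <- cavity_volume(unflatten_mesh(model$mean + s * m,
                                         model$n_circ, model$n_long))
      vm <- cavity_volume(unflatten_mesh(model$mean - s * m,
                                         model$n_circ, model$n_long))
      if (abs(vp - vm) > 1e-6 * base_vol) {
        flip <- vp < vm; decided <- TRUE
      }
    }
    if (!decided) flip <- m[which.max(abs(m))] < 0
    if (flip) model$modes[, k] <- -m
  }
  model
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: N=%d, D=%d, %d modes retained, first-%d variance %.1f%%\n",
              x$n_train, length(x$mean), x$n_retained, x$n_retained,
              100 * variance_explained(x, x$n_retained)))
  invisible(x)
}

as_shape_vector <- function(x, model) {
  if (inherits(x, "lv_mesh")) x <- flatten_mesh(x)
  if (length(x) != length(model$mean)) {
    stop("shape vector length does not match the model")
  }
  as.numeric(x)
}

#' Project a shape onto the retained modes
#'
#' Coefficients `c_j = M_j . (x - mean)` for the first `n_retained` modes;
#' these per-patient loadings are the candidate biomarkers fed to the
#' Cox-Lasso stage.
#'
#' @param model a `shape_model`.
#' @param x shape vector of model dimension, an `lv_mesh`, or an N x D
#'   matrix of shape vectors.
#' @return numeric vector of length `n_retained` (or N x n_retained matrix).
#' @export
project_shape <- function(model, x) {
  Mk <- model$modes[, seq_len(model$n_retained), drop = FALSE]
  if (is.matrix(x) && !inherits(x, "lv_mesh")) {
    if (ncol(x) != length(model$mean)) stop("shape vector length mismatch")
    return(sweep(x, 2, model$mean) %*% Mk)
  }
  as.numeric(crossprod(Mk, as_shape_vector(x, model) - model$mean))
}

#' Reconstruct a shape from mode coefficients
#'
#' `x = mean + sum_j c_j M_j`; with all retained coefficients this inverts
#' [project_shape()] on the retained subspace.
#'
#' @param model a `shape_model`.
#' @param coefficients up to `n_retained` mode coefficients.
#' @param as_mesh return an `lv_mesh` (requires lattice topology) rather
#'   than a shape vector.
#' @return shape vector or `lv_mesh`.
#' @export
reconstruct_shape <- function(model, coefficients, as_mesh = FALSE) {
  k <- length(coefficients)
  if (k > model$n_retained) stop("more coefficients than retained modes")
  x <- model$mean
  if (k > 0) {
    x <- x + as.vector(model$modes[, seq_len(k), drop = FALSE] %*%
                         as.numeric(coefficients))
  }
  if (as_mesh) {
    if (is.null(model$n_circ)) stop("model carries no lattice topology")
    return(unflatten_mesh(x, model$n_circ, model$n_long, rv_direction = 0))
  }
  x
}

#' Fraction of shape variance explained by the first k modes
#'
#' @param model a `shape_model`.
#' @param k number of leading modes.
#' @return fraction in (0, 1].
#' @export
variance_explained <- function(model, k) {
  if (k < 1 || k > length(model$eigenvalues)) stop("k out of range")
  sum(model$eigenvalues[seq_len(k)]) / sum(model$eigenvalues)
}

#' Exaggerate a direction in mode space
#'
#' Returns the mesh at `mean + n_sd * sigma_d * (M d)` where `d` is a unit
#' direction in retained-mode space and `sigma_d` the training-sample SD of
#' the projected score along `d` (for a single mode, its eigenvalue square
#' root).  The +/-3 SD meshes of a mode are the standard way to visualize
#' what anatomy it encodes.
#'
#' @param model a `shape_model` with lattice topology.
#' @param direction unit vector in mode space (length `n_retained`), or a
#'   single mode index.
#' @param n_sd how many SDs to move (may be negative).
#' @return an `lv_mesh`.
#' @export
exaggerate_mode <- function(model, direction, n_sd) {
  K <- model$n_retained
  if (length(direction) == 1L && direction == round(direction)) {
    j <- as.integer(direction)
    if (j < 1 || j > K) stop("mode index out of range")
    d <- rep(0, K); d[j] <- 1
  } else {
    d <- as.numeric(direction)
    if (length(d) != K) stop("direction must have length n_retained")
  }
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("zero direction")
  d <- d / nd
  sigma <- sqrt(sum(d^2 * model$eigenvalues[seq_len(K)]))
  x <- model$mean + n_sd * sigma *
    as.vector(model$modes[, seq_len(K), drop = FALSE] %*% d)
  if (is.null(model$n_circ)) stop("model carries no lattice topology")
  unflatten_mesh(x, model$n_circ, model$n_long, rv_direction = 0)
}

#' Spearman correlations between mode coefficients and cohort variables
#'
#' Spearman rho with two-sided t-test significance,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom,
#' using pairwise-complete observations.  Constant columns give `NA` (rho
#' undefined).  At n = 156 the implied significance threshold is
#' |rho| >= 0.157 at p < 0.05.
#'
#' @param coefficients N x K matrix of mode coefficients.
#' @param cohort data.frame of variables (continuous or 0/1).
#' @param variables columns of `cohort` to use (default: all numeric).
#' @param min_pairs minimum complete pairs per cell (default 10).
#' @return list with matrices `rho` and `p` (modes x variables).
#' @export
mode_variable_correlations <- function(coefficients, cohort,
                                       variables = NULL, min_pairs = 10L) {
  co <- as.matrix(coefficients)
  if (is.null(variables)) {
    variables <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  }
  K <- ncol(co)
  rho <- p <- matrix(NA_real_, K, length(variables),
                     dimnames = list(colnames(co) %||% paste0("M", seq_len(K)),
                                     variables))
  for (j in seq_along(variables)) {
    v <- as.numeric(cohort[[variables[j]]])
    for (k in seq_len(K)) {
      ok <- stats::complete.cases(co[, k], v)
      n <- sum(ok)
      if (n < min_pairs) next
      if (stats::sd(v[ok]) == 0 || stats::sd(co[ok, k]) == 0) next
      r <- stats::cor(co[ok, k], v[ok], method = "spearman")
      rho[k, j] <- r
      if (abs(r) < 1) {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        p[k, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
      } else {
        p[k, j] <- 0
      }
    }
  }
  list(rho = rho, p = p)
}
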