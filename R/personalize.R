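#' Remove supra-basal slices
#'
#' Slices above the slice carrying the right-ventricular landmark (valve
#' plane and atrial images) are removed; the landmark's slice is retained as
#' the most basal.  Mirrors the standard pre-processing rule that images
#' above the most basal RV slice are discarded before shape fitting.
#'
#' @param stack a `contour_stack`.
#' @return truncated, revalidated `contour_stack`.
#' @export
truncate_basal <- function(stack) {
  if (length(stack$rv_landmark) != 3 || any(!is.finite(stack$rv_landmark))) {
    stop("rv_landmark required for basal truncation")
  }
  z <- vapply(stack$slices, function(s) s$z, numeric(1))
  li <- which.min(abs(z - stack$rv_landmark[3]))
  if (abs(z[li] - stack$rv_landmark[3]) > stack$slice_thickness) {
    if (stack$rv_landmark[3] < min(z)) {
      stop("rv_landmark lies below the most apical slice")
    }
  }
  keep <- which(z <= z[li] + 1e-9)
  contour_stack(stack$patient_id, stack$slices[keep],
                stack$slice_thickness, stack$in_plane_res,
                stack$rv_landmark,
                landmark_slice = li)
}

slice_z <- function(stack) vapply(stack$slices, function(s) s$z, numeric(1))

# apex position from the apical radius trend: for an ellipsoid cap the
# squared cavity radius is ~linear in z near the apex, so extrapolating
# r^2 -> 0 from the two most apical slices locates the apex far better
# than a fixed half-slice margin (which carries a sawtooth bias of up to
# one slice thickness in the cavity length)
estimate_apex_z <- function(stack) {
  z <- slice_z(stack)
  th <- stack$slice_thickness
  r2 <- vapply(stack$slices[1:2], function(s) {
    ctr <- colMeans(s$endo)
    mean(rowSums(sweep(s$endo, 2, ctr)^2))
  }, numeric(1))
  slope <- (r2[2] - r2[1]) / (z[2] - z[1])
  z0 <- if (slope > 1e-9) z[1] - r2[1] / slope else z[1] - 0.5 * th
  min(max(z0, z[1] - 1.5 * th), z[1] - 0.3 * th)
}

# in-plane radii of a contour along a given frame angle: for points roughly
# uniform in angle on an ellipse, the semi-axes are sqrt(2) times the SDs
# along the frame axes.  The frame is the RV-landmark direction rather than
# the (rotationally unstable on near-circular contours) principal axes, so
# the template lattice is oriented consistently across a cohort.
contour_radii <- function(poly, angle) {
  ctr <- colMeans(poly)
  rel <- sweep(poly, 2, ctr) %*%
    matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)
  list(ctr = ctr, radii = sqrt(2) * apply(rel, 2, stats::sd), angle = angle)
}

#' Size and place the template from a truncated stack
#'
#' Builds a truncated half-ellipsoid whose apex-to-base extent matches the
#' stack (base at a half-slice margin above the most basal slice; apex
#' extrapolated from the apical radius trend, see the source note on the
#' sawtooth bias of fixed margins) and whose mid-cavity diameters match the
#' mid-slice contours by second-moment matching; wall thickness is
#' initialized from the mid-slice epi-endo mean radius difference.  The
#' lattice is oriented by the RV-landmark direction (stable across
#' near-circular slices, unlike principal axes) and translated onto the
#' contour centroid, giving the starting point for the non-rigid fit.
#'
#' @param stack a truncated `contour_stack`.
#' @param n_circ,n_long lattice resolution of the fitted mesh.
#' @param c_over_h ratio of ellipsoid long semi-axis to cavity height
#'   (controls how far below the equator the base plane sits).
#' @return an `lv_mesh` positioned in stack coordinates.
#' @export
initialize_template <- function(stack, n_circ = 24L, n_long = 16L,
                                c_over_h = 1.15) {
  validate_contour_stack(stack)
  z <- slice_z(stack)
  th <- stack$slice_thickness
  z_apex <- estimate_apex_z(stack)
  z_base <- max(z) + 0.5 * th
  h <- z_base - z_apex
  cc <- c_over_h * h
  ctrs0 <- t(vapply(stack$slices, function(s) colMeans(s$endo), numeric(2)))
  rv_ang <- atan2(stack$rv_landmark[2] - mean(ctrs0[, 2]),
                  stack$rv_landmark[1] - mean(ctrs0[, 1]))
  mid <- which.min(abs(z - (z_apex + 0.6 * h)))  # mid-cavity slice
  en <- contour_radii(stack$slices[[mid]]$endo, rv_ang)
  ep <- contour_radii(stack$slices[[mid]]$epi, rv_ang)
  zr <- z[mid] - z_apex                           # height of mid slice
  shape_fac <- sqrt(zr * (2 * cc - zr)) / cc      # r(z)/a for the ellipsoid
  ab <- pmax(en$radii / shape_fac, 1)
  wall <- max(mean(ep$radii) - mean(en$radii), 1)
  tpl <- make_template(c(ab[1], ab[2], cc), wall_thickness = wall,
                       trunc_height = h, n_circ = n_circ, n_long = n_long)
  # center on the stack: xy from contour centroids, z so apex sits at
  # z_apex; lattice oriented by the RV landmark for cohort correspondence
  tpl <- transform_mesh(tpl, rotation_z(rv_ang),
                        c(colMeans(ctrs0), z_apex))
  tpl$rv_direction <- rv_ang
  tpl
}

# lattice graph Laplacian (one surface): ring neighbours, longitudinal
# neighbours, apex connected to the first ring; rows scaled by degree
lattice_laplacian <- function(n_circ, n_long) {
  nn <- n_surface_nodes(n_circ, n_long)
  A <- matrix(0, nn, nn)
  idx <- function(j, i) 1L + (j - 1L) * n_circ + ((i - 1L) %% n_circ) + 1L
  for (j in seq_len(n_long)) {
    for (i in seq_len(n_circ)) {
      k <- idx(j, i)
      nb <- c(idx(j, i + 1L), idx(j, i - 1L))
      if (j > 1L) nb <- c(nb, idx(j - 1L, i)) else nb <- c(nb, 1L)
      if (j < n_long) nb <- c(nb, idx(j + 1L, i))
      A[k, nb] <- 1
    }
  }
  A[1L, idx(1L, seq_len(n_circ))] <- 1
  deg <- rowSums(A)
  diag(nrow = nn) - A / deg
}

# correspondence of contour points to the lattice surface at matching z and
# circumferential angle: each contour point maps to a bilinear combination
# of <= 4 nodes (the bracketing columns' plane crossings).  Returns the
# sparse design matrix rows and the current residuals.
surface_correspondence <- function(nodes, n_circ, n_long, pts3) {
  cols <- surface_columns(nodes, n_circ, n_long)
  nn <- n_surface_nodes(n_circ, n_long)
  A <- matrix(0, nrow(pts3), nn)
  resid <- numeric(nrow(pts3))
  node_index <- function(i, seg_j) {
    # segment seg_j of a column polyline: 1 = apex->ring1, else ring(j-1)->ring(j)
    i <- ((i - 1L) %% n_circ) + 1L
    if (seg_j == 1L) c(1L, 1L + i)
    else c(1L + (seg_j - 2L) * n_circ + i, 1L + (seg_j - 1L) * n_circ + i)
  }
  for (z0 in unique(pts3[, 3])) {
    sel <- which(pts3[, 3] == z0)
    # crossing of every column with this plane
    cr <- lapply(cols, function(cxyz) {
      z <- cxyz[, 3]
      for (s in seq_len(nrow(cxyz) - 1L)) {
        if ((z[s] <= z0 && z0 <= z[s + 1L]) || (z[s + 1L] <= z0 && z0 <= z[s])) {
          t <- if (z[s + 1L] == z[s]) 0 else (z0 - z[s]) / (z[s + 1L] - z[s])
          return(list(seg = s, t = t,
                      xy = cxyz[s, 1:2] + t * (cxyz[s + 1L, 1:2] - cxyz[s, 1:2])))
        }
      }
      NULL
    })
    ok <- !vapply(cr, is.null, logical(1))
    if (sum(ok) < 3) { resid[sel] <- NA; next }
    okw <- which(ok)
    xy <- do.call(rbind, lapply(cr[okw], `[[`, "xy"))
    ctr <- colMeans(xy)
    cang <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
    ordc <- order(cang)
    for (p in sel) {
      pang <- atan2(pts3[p, 2] - ctr[2], pts3[p, 1] - ctr[1])
      pos <- findInterval(pang, cang[ordc])
      ia <- if (pos == 0L) length(ordc) else pos
      ib <- if (ia == length(ordc)) 1L else ia + 1L
      ca <- cr[[okw[ordc[ia]]]]; cb <- cr[[okw[ordc[ib]]]]
      a1 <- cang[ordc[ia]]; a2 <- cang[ordc[ib]]
      gap <- (a2 - a1) %% (2 * pi); off <- (pang - a1) %% (2 * pi)
      s <- if (gap < 1e-12) 0 else min(max(off / gap, 0), 1)
      na <- node_index(okw[ordc[ia]], ca$seg)
      nb <- node_index(okw[ordc[ib]], cb$seg)
      w <- c((1 - s) * (1 - ca$t), (1 - s) * ca$t,
             s * (1 - cb$t), s * cb$t)
      ii <- c(na, nb)
      for (q in seq_along(ii)) A[p, ii[q]] <- A[p, ii[q]] + w[q]
      pred <- w %*% nodes[ii, 1:2, drop = FALSE]
      resid[p] <- sqrt(sum((pts3[p, 1:2] - pred)^2))
    }
  }
  list(A = A, resid = resid)
}

stack_points <- function(stack, surface) {
  do.call(rbind, lapply(stack$slices, function(s) {
    cbind(s[[surface]], s$z)
  }))
}

#' Non-rigid fit of the template to a contour stack
#'
#' Iteratively matches every contour point to the surface point at the same
#' slice height and circumferential angle (epicardial points to the
#' epicardial surface, endocardial to endocardial), then solves, per
#' surface, the linear least-squares problem
#' \deqn{\min_x \|A x - b\|^2 + w \|L (x - x_0)\|^2}
#' where `A` interpolates lattice nodes to the matched contour points, `L`
#' is the lattice Laplacian and `x_0` the initialization -- a Gauss-Newton
#' step with ICP-style re-matching.  Iteration stops when the RMS node
#' change drops below `tol` mm, when the mean distance stops decreasing
#' (the previous, better iterate is kept), or at `max_iter`.
#'
#' @param mesh initialized `lv_mesh` (see [initialize_template()]).
#' @param stack truncated `contour_stack`.
#' @param smoothing_weight Laplacian penalty weight `w` (>= 0); the default
#'   0.3 sits at the L-curve elbow on synthetic fixtures.
#' @param max_iter,tol stopping controls.
#' @return list with `mesh` (fitted `lv_mesh`) and `report` (a `fit_report`:
#'   `mean_distance`, `sd_distance` in mm, `iterations`, `converged`).
#' @export
fit_to_contours <- function(mesh, stack, smoothing_weight = 0.3,
                            max_iter = 100L, tol = 1e-3) {
  if (smoothing_weight < 0) stop("smoothing_weight must be non-negative")
  validate_contour_stack(stack)
  L <- lattice_laplacian(mesh$n_circ, mesh$n_long)
  LtL <- crossprod(L)
  pts <- list(endo = stack_points(stack, "endo"),
              epi = stack_points(stack, "epi"))
  x0 <- list(endo = mesh$endo, epi = mesh$epi)
  cur <- x0
  best <- cur; best_err <- Inf; best_resid <- NULL
  iters <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    resids <- NULL
    nxt <- cur
    for (surf in c("endo", "epi")) {
      co <- surface_correspondence(cur[[surf]], mesh$n_circ, mesh$n_long,
                                   pts[[surf]])
      keep <- !is.na(co$resid)
      A <- co$A[keep, , drop = FALSE]
      M <- crossprod(A) + smoothing_weight * LtL
      rhs <- crossprod(A, pts[[surf]][keep, , drop = FALSE]) +
        smoothing_weight * (LtL %*% x0[[surf]])
      nxt[[surf]] <- solve(M, rhs)
      resids <- c(resids, co$resid[keep])
    }
    err <- mean(resids)
    if (err < best_err - 1e-12) {
      best <- cur; best_err <- err; best_resid <- resids
    } else if (it > 1L) {
      # error plateaued: keep the previous accepted iterate; this is a
      # fixed point of the ICP iteration, i.e. convergence
      converged <- TRUE
      break
    }
    delta <- sqrt(mean((rbind(nxt$endo, nxt$epi) - rbind(cur$endo, cur$epi))^2))
    cur <- nxt
    if (delta < tol) { best <- cur; converged <- TRUE
      # final residuals on the accepted mesh
      fr <- NULL
      for (surf in c("endo", "epi")) {
        co <- surface_correspondence(cur[[surf]], mesh$n_circ, mesh$n_long,
                                     pts[[surf]])
        fr <- c(fr, co$resid[!is.na(co$resid)])
      }
      best_resid <- fr
      break
    }
  }
  out <- lv_mesh(best$endo, best$epi, mesh$n_circ, mesh$n_long)
  com <- colMeans(rbind(out$endo, out$epi))
  out$rv_direction <- atan2(stack$rv_landmark[2] - com[2],
                            stack$rv_landmark[1] - com[1])
  report <- structure(list(mean_distance = mean(best_resid),
                           sd_distance = stats::sd(best_resid),
                           iterations = iters, converged = converged),
                      class = "fit_report")
  list(mesh = out, report = report)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit: %.3f +/- %.3f mm after %d iterations (%s)\n",
              x$mean_distance, x$sd_distance, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Rigid cohort alignment
#'
#' Each mesh is translated so its centre of mass (mean of all nodes) sits at
#' the origin and rotated about z so +x points from the LV centre of mass
#' towards the right-ventricular landmark; +z (apex to base, the slice
#' normal) is left untouched and no scaling is applied, so size remains part
#' of the shape signal.
#'
#' @param mesh an `lv_mesh` carrying `rv_direction`.
#' @return aligned `lv_mesh` (`rv_direction` becomes 0).
#' @export
align_mesh <- function(mesh) {
  if (is.na(mesh$rv_direction)) {
    stop("mesh has no RV landmark direction; cannot align")
  }
  com <- colMeans(rbind(mesh$endo, mesh$epi))
  m <- transform_mesh(mesh, diag(3), -com)
  transform_mesh(m, rotation_z(-m$rv_direction))
}

#' @rdname align_mesh
#' @param meshes list of `lv_mesh`.
#' @export
align_cohort <- function(meshes) lapply(meshes, align_mesh)
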