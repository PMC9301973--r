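#' Fixed-topology two-surface left-ventricular mesh
#'
#' An `lv_mesh` holds the endocardial and epicardial surfaces of one left
#' ventricle on a shared structured lattice: one apex node plus `n_long`
#' rings of `n_circ` nodes per surface, ordered apex to base.  Identical
#' lattice topology across a cohort gives node-wise correspondence, which is
#' the precondition for building a statistical shape model by PCA.
#'
#' Coordinates are millimetres in a right-handed frame: +z runs apex to base
#' (perpendicular to the short-axis slice planes), and after cohort alignment
#' +x points from the LV centre of mass towards the right-ventricular
#' landmark.
#'
#' @param endo,epi numeric matrices, `(n_circ * n_long + 1) x 3`; row 1 is
#'   the apex node, then rings apex to base, each ring ordered by increasing
#'   circumferential angle.
#' @param n_circ,n_long lattice resolution (nodes per ring, number of rings).
#' @param rv_direction angle (radians) in the xy-plane from +x towards the
#'   right-ventricular landmark, or `NA` if unknown.
#' @return an object of class `lv_mesh`.
#' @export
lv_mesh <- function(endo, epi, n_circ, n_long, rv_direction = NA_real_) {
  n_nodes <- n_circ * n_long + 1L
  stopifnot(is.matrix(endo), is.matrix(epi))
  if (nrow(endo) != n_nodes || nrow(epi) != n_nodes || ncol(endo) != 3L ||
      ncol(epi) != 3L) {
    stop("node matrices must be (n_circ * n_long + 1) x 3")
  }
  structure(
    list(endo = unname(endo), epi = unname(epi),
         n_circ = as.integer(n_circ), n_long = as.integer(n_long),
         rv_direction = rv_direction),
    class = "lv_mesh"
  )
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("lv_mesh: %d x %d lattice (%d nodes/surface), z in [%.1f, %.1f] mm\n",
              x$n_circ, x$n_long, nrow(x$endo),
              min(x$epi[, 3]), max(x$endo[, 3])))
  invisible(x)
}

n_surface_nodes <- function(n_circ, n_long) n_circ * n_long + 1L

#' Build the idealized truncated half-ellipsoid LV template
#'
#' The endocardial surface is the cap of an ellipsoid with semi-axes
#' `semi_axes = c(a, b, c)` (mm), apex pole at z = 0 and cut by the basal
#' plane z = `trunc_height`.  The epicardial surface is offset outward from
#' the endocardium by `wall_thickness` along the exact ellipsoid normal, so
#' the template wall thickness equals `wall_thickness` everywhere.  Rings are
#' spaced uniformly in polar angle from the apex, which keeps facets well
#' shaped near the apex.
#'
#' @param semi_axes numeric length-3, ellipsoid semi-axes (a, b, c) in mm.
#' @param wall_thickness myocardial wall thickness in mm.
#' @param trunc_height apex-to-base cavity height in mm; must be below the
#'   long semi-axis `c`.
#' @param n_circ,n_long lattice resolution; defaults 24 x 16 give a shape
#'   vector of length 3 * 2 * (24 * 16 + 1) = 2310.
#' @return an `lv_mesh`.
#' @examples
#' tpl <- make_template(c(25, 25, 80), wall_thickness = 8, trunc_height = 70)
#' @export
make_template <- function(semi_axes, wall_thickness, trunc_height,
                          n_circ = 24L, n_long = 16L) {
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0)) {
    stop("semi_axes must be three positive numbers")
  }
  if (!is.finite(wall_thickness) || wall_thickness <= 0) {
    stop("wall_thickness must be positive")
  }
  if (!is.finite(trunc_height) || trunc_height <= 0) {
    stop("trunc_height must be positive")
  }
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  if (trunc_height >= cc) {
    stop("trunc_height must be smaller than the long semi-axis")
  }
  # polar angle of the basal plane: z = c (1 - cos(phi))
  phi_max <- acos(1 - trunc_height / cc)
  phi <- phi_max * seq_len(n_long) / n_long
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ

  endo <- matrix(0, n_surface_nodes(n_circ, n_long), 3L)
  epi <- endo
  # apex nodes: endo at origin, epi offset along -z (outward normal at pole)
  epi[1L, ] <- c(0, 0, -wall_thickness)
  k <- 2L
  for (j in seq_len(n_long)) {
    sp <- sin(phi[j]); cp <- cos(phi[j])
    x <- a * sp * cos(theta)
    y <- b * sp * sin(theta)
    z <- cc * (1 - cp)
    endo[k:(k + n_circ - 1L), ] <- cbind(x, y, z)
    # outward ellipsoid normal at (x, y, z): (x/a^2, y/b^2, (z - c)/c^2)
    nx <- x / a^2; ny <- y / b^2; nz <- (z - cc) / cc^2
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    epi[k:(k + n_circ - 1L), ] <-
      cbind(x + wall_thickness * nx / nn,
            y + wall_thickness * ny / nn,
            z + wall_thickness * nz / nn)
    k <- k + n_circ
  }
  lv_mesh(endo, epi, n_circ, n_long, rv_direction = 0)
}

#' Flatten a mesh to its shape vector
#'
#' Concatenates endocardial then epicardial node coordinates in lattice
#' order, each node as (x, y, z).  The inverse is [unflatten_mesh()]; the
#' fixed ordering is what gives cross-patient correspondence of vector
#' entries.
#'
#' @param mesh an `lv_mesh`.
#' @return numeric vector of length `3 * 2 * (n_circ * n_long + 1)`.
#' @export
flatten_mesh <- function(mesh) {
  c(as.vector(t(mesh$endo)), as.vector(t(mesh$epi)))
}

#' @rdname flatten_mesh
#' @param x shape vector as produced by [flatten_mesh()].
#' @param n_circ,n_long lattice resolution of the target mesh.
#' @param rv_direction carried through to the rebuilt mesh.
#' @export
unflatten_mesh <- function(x, n_circ, n_long, rv_direction = NA_real_) {
  n_nodes <- n_surface_nodes(n_circ, n_long)
  if (length(x) != 6L * n_nodes) {
    stop("shape vector length does not match lattice topology")
  }
  endo <- matrix(x[seq_len(3L * n_nodes)], ncol = 3L, byrow = TRUE)
  epi <- matrix(x[-seq_len(3L * n_nodes)], ncol = 3L, byrow = TRUE)
  lv_mesh(endo, epi, n_circ, n_long, rv_direction)
}

#' Triangulation of one lattice surface
#'
#' Node 1 is the apex; ring `j` node `i` has index `1 + (j-1) n_circ + i`.
#' Faces are an apex fan plus two triangles per lattice quad; orientation is
#' consistent across the surface (outward for a surface wound like the
#' template endocardium).
#'
#' @param n_circ,n_long lattice resolution.
#' @return integer matrix, one face per row, three node indices per face.
#' @export
surface_triangles <- function(n_circ, n_long) {
  idx <- function(j, i) 1L + (j - 1L) * n_circ + ((i - 1L) %% n_circ) + 1L
  faces <- vector("list", n_long)
  i <- seq_len(n_circ)
  # apex fan
  faces[[1L]] <- cbind(1L, idx(1L, i + 1L), idx(1L, i))
  for (j in seq_len(n_long - 1L)) {
    a <- idx(j, i); b <- idx(j, i + 1L)
    cth <- idx(j + 1L, i); dth <- idx(j + 1L, i + 1L)
    faces[[j + 1L]] <- rbind(cbind(a, dth, cth), cbind(a, b, dth))
  }
  do.call(rbind, faces)
}

# Per-node outward normals of one surface (nodes: (n_circ*n_long+1) x 3).
# Face normals are area-averaged onto nodes, then each node normal is
# flipped, if needed, to point away from the surface's own z-axis centroid
# line (outward for a tube-like LV surface).
surface_node_normals <- function(nodes, n_circ, n_long) {
  tri <- surface_triangles(n_circ, n_long)
  v1 <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  v2 <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  fn <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  nrm <- matrix(0, nrow(nodes), 3L)
  for (kcol in 1:3) {
    for (vcol in 1:3) {
      acc <- tapply(fn[, kcol], tri[, vcol], sum)
      ii <- as.integer(names(acc))
      nrm[ii, kcol] <- nrm[ii, kcol] + acc
    }
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  # orient outward: positive dot product with (node - axis point at same z)
  ctr <- colMeans(nodes)
  radial <- nodes - matrix(ctr, nrow(nodes), 3L, byrow = TRUE)
  flip <- rowSums(nrm * radial) < 0
  # apex node: outward means -z (towards the apex, away from the cavity)
  flip[1L] <- nrm[1L, 3L] > 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

# z-range helpers
mesh_base_z <- function(mesh) {
  ring <- mesh$endo[(nrow(mesh$endo) - mesh$n_circ + 1L):nrow(mesh$endo), ]
  mean(ring[, 3])
}
mesh_apex_z <- function(mesh) mesh$epi[1L, 3L]
endo_apex_z <- function(mesh) mesh$endo[1L, 3L]

#' Apply a rigid transform to a mesh
#'
#' @param mesh an `lv_mesh`.
#' @param rotation 3x3 rotation matrix (applied first).
#' @param translation length-3 translation (applied second), mm.
#' @return transformed `lv_mesh`; `rv_direction` is updated for rotations
#'   about the z axis and invalidated otherwise.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(nodes) {
    sweep(nodes %*% t(rotation), 2L, -translation)
  }
  rv <- mesh$rv_direction
  if (!is.na(rv)) {
    # track the landmark direction through the in-plane part of the rotation
    d <- rotation %*% c(cos(rv), sin(rv), 0)
    rv <- if (abs(d[3]) < 1e-9) atan2(d[2], d[1]) else NA_real_
  }
  lv_mesh(tr(mesh$endo), tr(mesh$epi), mesh$n_circ, mesh$n_long, rv)
}

rotation_z <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
}

same_topology <- function(a, b) {
  a$n_circ == b$n_circ && a$n_long == b$n_long
}
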