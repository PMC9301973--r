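#' LV cavity (blood-pool) volume
#'
#' Volume enclosed by the endocardial surface closed off by its basal plane,
#' computed with the divergence theorem over the triangulated surface plus a
#' fan cap over the base ring.  This is the end-diastolic blood-pool volume
#' BPvol when evaluated on an end-diastolic mesh.
#'
#' @param mesh an aligned `lv_mesh`.
#' @return volume in mL.
#' @export
cavity_volume <- function(mesh) {
  nodes <- mesh$endo
  if (any(!is.finite(nodes))) stop("endocardial surface is not watertight: non-finite nodes")
  tri <- surface_triangles(mesh$n_circ, mesh$n_long)
  ring <- nodes[(nrow(nodes) - mesh$n_circ + 1L):nrow(nodes), , drop = FALSE]
  ctr <- colMeans(ring)
  # base cap: fan from the base-ring centroid
  n0 <- nrow(nodes)
  i <- seq_len(mesh$n_circ)
  ip <- c(i[-1L], i[1L])
  cap <- cbind(n0 + 1L, n0 - mesh$n_circ + i, n0 - mesh$n_circ + ip)
  allnodes <- rbind(nodes, ctr)
  alltri <- rbind(tri, cap)
  v1 <- allnodes[alltri[, 1], , drop = FALSE]
  v2 <- allnodes[alltri[, 2], , drop = FALSE]
  v3 <- allnodes[alltri[, 3], , drop = FALSE]
  det6 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
    v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  abs(sum(det6)) / 6 / 1000
}

#' Apex-to-base LV length
#'
#' z-extent from the epicardial apex node to the basal plane (mean z of the
#' endocardial base ring), in mm.  Assumes an aligned mesh (+z apex to base).
#'
#' @param mesh an aligned `lv_mesh`.
#' @return length in mm.
#' @export
lv_length <- function(mesh) {
  mesh_base_z(mesh) - mesh_apex_z(mesh)
}

# Vectorized Moller-Trumbore: one ray against all triangles of a surface.
# Returns the smallest positive hit distance, or NA if the ray misses.
ray_surface_distance <- function(origin, dir, nodes, tri) {
  eps <- 1e-9
  p0 <- nodes[tri[, 1], , drop = FALSE]
  e1 <- nodes[tri[, 2], , drop = FALSE] - p0
  e2 <- nodes[tri[, 3], , drop = FALSE] - p0
  # h = dir x e2
  h1 <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  h2 <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  h3 <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  a <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(a) > eps
  s1 <- origin[1] - p0[, 1]; s2 <- origin[2] - p0[, 2]; s3 <- origin[3] - p0[, 3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / a
  ok <- ok & u >= -1e-6 & u <= 1 + 1e-6
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  v <- (dir[1] * q1 + dir[2] * q2 + dir[3] * q3) / a
  ok <- ok & v >= -1e-6 & (u + v) <= 1 + 1e-6
  t <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / a
  ok <- ok & t > 1e-6
  if (!any(ok)) return(NA_real_)
  min(t[ok])
}

# thickness at every endocardial lattice site by casting the outward
# endocardial normal against the triangulated epicardial surface
wall_thickness_sites <- function(mesh) {
  nrm <- surface_node_normals(mesh$endo, mesh$n_circ, mesh$n_long)
  tri <- surface_triangles(mesh$n_circ, mesh$n_long)
  vapply(seq_len(nrow(mesh$endo)), function(k) {
    ray_surface_distance(mesh$endo[k, ], nrm[k, ], mesh$epi, tri)
  }, numeric(1))
}

#' Mean myocardial wall thickness
#'
#' Mean, over endocardial lattice sites, of the distance from the site to the
#' epicardial surface along the local outward endocardial normal.  Sites
#' whose normal ray misses the epicardium are excluded with a warning; more
#' than 10\% excluded is an error (the mesh is then too distorted to trust).
#'
#' @param mesh an aligned `lv_mesh`.
#' @return mean thickness in mm.
#' @export
mean_wall_thickness <- function(mesh) {
  th <- wall_thickness_sites(mesh)
  miss <- sum(is.na(th))
  if (miss > 0) {
    if (miss > 0.1 * length(th)) {
      stop(sprintf("wall thickness undefined at %d of %d sites (>10%%)",
                   miss, length(th)))
    }
    warning(sprintf("wall thickness: %d of %d sites excluded (normal ray missed epicardium)",
                    miss, length(th)))
  }
  mean(th, na.rm = TRUE)
}

#' LV sphericity
#'
#' Cavity volume divided by the volume of a sphere whose diameter equals the
#' LV length: `sphericity = BPvol / ((4/3) pi (L/2)^3)`.  Dimensionless; 1
#' for a cavity filling the diameter-matched sphere.
#'
#' @param bpvol cavity volume, mL.
#' @param length apex-to-base length, mm.
#' @return sphericity (dimensionless).
#' @export
sphericity <- function(bpvol, length) {
  if (!is.finite(bpvol) || bpvol <= 0) stop("bpvol must be positive")
  if (!is.finite(length) || length <= 0) stop("length must be positive")
  sphere_ml <- (4 / 3) * pi * (length / 2)^3 / 1000
  bpvol / sphere_ml
}

#' All scalar geometry metrics of a mesh
#'
#' @param mesh an aligned `lv_mesh`.
#' @return data.frame with columns `bpvol` (mL), `length` (mm),
#'   `mean_wall_thickness` (mm), `sphericity`.
#' @export
geometry_metrics <- function(mesh) {
  v <- cavity_volume(mesh)
  l <- lv_length(mesh)
  data.frame(bpvol = v, length = l,
             mean_wall_thickness = mean_wall_thickness(mesh),
             sphericity = sphericity(v, l))
}

# deterministic 16-segment assignment for every endocardial ring site.
# Longitudinal thirds (basal/mid/apical) are equal z-bands of the ring-node
# z-range of `mesh`; basal and mid rings split into sextants, the apical ring
# into quadrants, by angle from +x (the RV direction after alignment),
# counter-clockwise.  Apex node itself is unassigned (NA): the cap is a
# single node, hence 16 segments rather than 17.
aha_segments <- function(mesh) {
  n <- nrow(mesh$endo)
  seg <- rep(NA_integer_, n)
  ring <- 2:n
  z <- mesh$endo[ring, 3]
  zb <- min(z) + (max(z) - min(z)) * c(1 / 3, 2 / 3)
  band <- ifelse(z > zb[2], 1L, ifelse(z > zb[1], 2L, 3L)) # 1 basal, 2 mid, 3 apical
  ang <- atan2(mesh$endo[ring, 2], mesh$endo[ring, 1]) %% (2 * pi)
  sext <- pmin(floor(ang / (2 * pi) * 6), 5) + 1L
  quad <- pmin(floor(ang / (2 * pi) * 4), 3) + 1L
  seg[ring] <- ifelse(band == 1L, sext,
                      ifelse(band == 2L, 6L + sext, 12L + quad))
  seg
}

#' Bullseye map of wall-thickness change between two meshes
#'
#' Per-site wall-thickness difference (`mesh_b` minus `mesh_a`) averaged
#' within each of 16 AHA-style segments: basal 1-6 and mid 7-12 sextants,
#' apical 13-16 quadrants, with longitudinal thirds by z and angles measured
#' from +x (towards the RV) counter-clockwise.  Used to display where an
#' exaggerated shape mode thins or thickens the wall.
#'
#' @param mesh_a,mesh_b aligned `lv_mesh` objects sharing topology;
#'   differences are b minus a.
#' @return object of class `bullseye_map`: list with `values` (16 segment
#'   means, mm) and `convention`.
#' @export
bullseye_thickness_delta <- function(mesh_a, mesh_b) {
  if (!same_topology(mesh_a, mesh_b)) stop("meshes differ in lattice topology")
  d <- wall_thickness_sites(mesh_b) - wall_thickness_sites(mesh_a)
  seg <- aha_segments(mesh_a)
  vals <- vapply(1:16, function(s) mean(d[seg == s], na.rm = TRUE), numeric(1))
  structure(list(values = vals,
                 convention = "16 AHA segments: basal 1-6, mid 7-12 sextants, apical 13-16 quadrants; z-thirds; angle CCW from +x (RV direction)"),
            class = "bullseye_map")
}

#' @export
print.bullseye_map <- function(x, ...) {
  cat("bullseye (mm): basal", sprintf("%.2f", x$values[1:6]), "\n")
  cat("              mid  ", sprintf("%.2f", x$values[7:12]), "\n")
  cat("              apex ", sprintf("%.2f", x$values[13:16]), "\n")
  invisible(x)
}
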