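CONTOUR_SCHEMA <- "lv-contours-1"

#' Per-patient short-axis contour stack
#'
#' Ordered stack of segmented end-diastolic contours: per slice one
#' epicardial and one endocardial polygon (open vertex lists, implicitly
#' closed), plus the slice geometry and the right-ventricular landmark point
#' that breaks the circumferential symmetry of the LV and marks the most
#' basal slice.  Slices are stored apex to base (strictly increasing z).
#'
#' Validation rejects (rather than repairs) stacks with fewer than 3 slices,
#' non-monotone z, self-intersecting polygons, an endocardial contour not
#' strictly inside its epicardial contour, or a landmark strictly inside the
#' epicardium of its slice.
#'
#' @param patient_id character id.
#' @param slices list of `list(z, epi, endo)`; `epi`/`endo` are m x 2
#'   matrices of (x, y) vertices in mm.
#' @param slice_thickness,in_plane_res acquisition geometry, mm.
#' @param rv_landmark numeric (x, y, z), mm.
#' @param landmark_slice optional integer bookkeeping: apex-to-base index of
#'   the slice carrying the landmark (generators record it; readers recover
#'   it from z).
#' @return object of class `contour_stack`.
#' @export
contour_stack <- function(patient_id, slices, slice_thickness, in_plane_res,
                          rv_landmark, landmark_slice = NA_integer_) {
  z <- vapply(slices, function(s) s$z, numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  if (!is.na(landmark_slice)) landmark_slice <- match(landmark_slice, ord)
  stack <- structure(
    list(patient_id = patient_id, slices = slices,
         slice_thickness = slice_thickness, in_plane_res = in_plane_res,
         rv_landmark = as.numeric(rv_landmark),
         landmark_slice = landmark_slice,
         units = "mm", schema = CONTOUR_SCHEMA),
    class = "contour_stack")
  validate_contour_stack(stack)
  stack
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("contour_stack %s: %d slices, z in [%.1f, %.1f] mm, thickness %.1f mm\n",
              x$patient_id, length(x$slices), x$slices[[1]]$z,
              x$slices[[length(x$slices)]]$z, x$slice_thickness))
  invisible(x)
}

# winding-number point-in-polygon; poly is m x 2, open vertex list
point_in_polygon <- function(pt, poly) {
  x <- poly[, 1] - pt[1]; y <- poly[, 2] - pt[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  ang <- atan2(x * yn - y * xn, x * xn + y * yn)
  abs(sum(ang)) > pi
}

# vectorized all-pairs proper-crossing test between non-adjacent edges
polygon_simple <- function(poly) {
  m <- nrow(poly)
  if (m < 3) return(FALSE)
  a <- poly; b <- poly[c(2:m, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  # Da[j, i] = signed area of point a_i relative to edge j; Db likewise for b_i
  Da <- outer(ex, a[, 2]) - ex * a[, 2] - (outer(ey, a[, 1]) - ey * a[, 1])
  Db <- outer(ex, b[, 2]) - ex * a[, 2] - (outer(ey, b[, 1]) - ey * a[, 1])
  straddle <- (Da * Db) < 0            # edge i straddles line of edge j
  cross <- straddle & t(straddle)
  # mask self and adjacent edge pairs (shared vertices)
  idx <- seq_len(m)
  adj <- abs(outer(idx, idx, "-")) %% m
  cross[adj <= 1 | adj == (m - 1)] <- FALSE
  !any(cross)
}

#' @rdname contour_stack
#' @param stack a `contour_stack` to validate; invariant violations are
#'   errors naming the offending slice.
#' @export
validate_contour_stack <- function(stack) {
  n <- length(stack$slices)
  if (n < 3) stop("contour stack must have at least 3 slices, got ", n)
  z <- vapply(stack$slices, function(s) s$z, numeric(1))
  if (any(diff(z) <= 0)) {
    stop("slice z-positions must be strictly monotone (slice ",
         which(diff(z) <= 0)[1] + 1L, ")")
  }
  for (i in seq_len(n)) {
    s <- stack$slices[[i]]
    for (nm in c("epi", "endo")) {
      p <- s[[nm]]
      if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p))) {
        stop("malformed ", nm, " polygon on slice ", i)
      }
      if (!polygon_simple(p)) {
        stop(nm, " polygon self-intersects on slice ", i)
      }
    }
    inside <- apply(s$endo, 1, point_in_polygon, poly = s$epi)
    if (!all(inside)) {
      stop("endocardial contour not strictly inside epicardial contour on slice ", i)
    }
  }
  if (length(stack$rv_landmark) != 3 || any(!is.finite(stack$rv_landmark))) {
    stop("missing or malformed rv_landmark")
  }
  li <- which.min(abs(z - stack$rv_landmark[3]))
  if (point_in_polygon(stack$rv_landmark[1:2], stack$slices[[li]]$epi)) {
    # allow on-contour points: reject only if clearly interior
    d <- min(sqrt(colSums((t(stack$slices[[li]]$epi) - stack$rv_landmark[1:2])^2)))
    if (d > 1e-6) {
      stop("rv_landmark lies strictly inside the epicardial contour of slice ", li)
    }
  }
  invisible(stack)
}

#' Read / write contour stacks as JSON
#'
#' One JSON document per patient with explicit units ("mm") and a schema
#' version.  Writing then reading reproduces all coordinates exactly
#' (17 significant digits), and writing a read stack reproduces the file
#' byte for byte under canonical apex-to-base ordering.
#'
#' @param stack a `contour_stack`.
#' @param path file path.
#' @return `read_contours` returns a validated `contour_stack`.
#' @export
write_contours <- function(stack, path) {
  doc <- list(
    schema = stack$schema, units = "mm",
    patient_id = stack$patient_id,
    slice_thickness = stack$slice_thickness,
    in_plane_res = stack$in_plane_res,
    rv_landmark = stack$rv_landmark,
    landmark_slice = stack$landmark_slice,
    slices = lapply(stack$slices, function(s) {
      list(z = s$z, epi = unname(s$epi), endo = unname(s$endo))
    })
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           na = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyVector = TRUE)
  if (is.null(doc$schema) || doc$schema != CONTOUR_SCHEMA) {
    stop("unrecognized contour schema version: ", doc$schema %||% "<none>")
  }
  if (is.null(doc$rv_landmark)) stop("missing rv_landmark")
  slices <- lapply(seq_len(nrow(doc$slices)), function(i) {
    list(z = doc$slices$z[i],
         epi = matrix(doc$slices$epi[[i]], ncol = 2),
         endo = matrix(doc$slices$endo[[i]], ncol = 2))
  })
  contour_stack(patient_id = doc$patient_id, slices = slices,
                slice_thickness = doc$slice_thickness,
                in_plane_res = doc$in_plane_res,
                rv_landmark = doc$rv_landmark,
                landmark_slice = doc$landmark_slice %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Export a mesh to VTK or OBJ
#'
#' Triangulated export of both surfaces in mm.  VTK (legacy ASCII polydata)
#' tags faces with a `surface` cell scalar (0 = endo, 1 = epi); OBJ uses
#' named `o endo` / `o epi` objects.  A degenerate mesh (epicardium touching
#' the endocardium) is exported with a warning rather than rejected, so
#' intermediate debugging geometry can still be inspected.
#'
#' @param mesh an `lv_mesh`.
#' @param path output path.
#' @param format `"vtk"` or `"obj"`.
#' @export
write_mesh <- function(mesh, path, format = c("vtk", "obj")) {
  format <- match.arg(format)
  nn <- nrow(mesh$endo)
  gap <- sqrt(rowSums((mesh$epi - mesh$endo)^2))
  if (min(gap) < 1e-9) {
    warning("degenerate mesh: epicardial surface touches endocardium")
  }
  tri <- surface_triangles(mesh$n_circ, mesh$n_long)
  pts <- rbind(mesh$endo, mesh$epi)
  faces <- rbind(tri, tri + nn)
  surf <- rep(0:1, each = nrow(tri))
  if (format == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 "lvshape LV mesh, units mm", "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(pts))), con)
    writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(faces), 4L * nrow(faces)), con)
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                       faces[, 3] - 1L), con)
    writeLines(c(sprintf("CELL_DATA %d", nrow(faces)),
                 "SCALARS surface int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(surf), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# lvshape LV mesh, units mm", con)
    writeLines("o endo", con)
    writeLines(sprintf("v %.9g %.9g %.9g",
                       mesh$endo[, 1], mesh$endo[, 2], mesh$endo[, 3]), con)
    writeLines(sprintf("f %d %d %d", tri[, 1], tri[, 2], tri[, 3]), con)
    writeLines("o epi", con)
    writeLines(sprintf("v %.9g %.9g %.9g",
                       mesh$epi[, 1], mesh$epi[, 2], mesh$epi[, 3]), con)
    writeLines(sprintf("f %d %d %d", tri[, 1] + nn, tri[, 2] + nn,
                       tri[, 3] + nn), con)
  }
  invisible(path)
}

#' Re-import an OBJ mesh written by [write_mesh()]
#'
#' @param path OBJ file path.
#' @param n_circ,n_long lattice topology of the exported mesh.
#' @return an `lv_mesh`.
#' @export
read_mesh_obj <- function(path, n_circ, n_long) {
  lines <- readLines(path)
  v <- lines[startsWith(lines, "v ")]
  xyz <- do.call(rbind, lapply(strsplit(v, " +"), function(p) as.numeric(p[2:4])))
  nn <- n_surface_nodes(n_circ, n_long)
  if (nrow(xyz) != 2L * nn) stop("vertex count does not match topology")
  lv_mesh(xyz[seq_len(nn), ], xyz[-seq_len(nn), ], n_circ, n_long)
}

#' Read and validate a cohort table
#'
#' The CSV must carry `follow_up_years` and `event` columns; optional
#' `icd_time_years` / `crt_time_years` device implant times must not exceed
#' follow-up.  "NA" entries become missing values.  Validation rejects, with
#' the offending patient ids, rather than repairing.
#'
#' @param path CSV path.
#' @return data.frame (the validated cohort table).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame (validated in place).
#' @export
validate_cohort <- function(cohort) {
  for (col in c("follow_up_years", "event")) {
    if (!col %in% names(cohort)) stop("missing required column: ", col)
  }
  if (any(is.na(cohort$follow_up_years)) || any(cohort$follow_up_years <= 0)) {
    stop("follow_up_years must be positive and complete")
  }
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0/1")
  ids <- if ("patient_id" %in% names(cohort)) cohort$patient_id
         else as.character(seq_len(nrow(cohort)))
  for (col in c("icd_time_years", "crt_time_years")) {
    if (col %in% names(cohort)) {
      bad <- which(!is.na(cohort[[col]]) &
                   cohort[[col]] > cohort$follow_up_years + 1e-9)
      if (length(bad)) {
        stop(col, " after follow-up for patients: ",
             paste(ids[bad], collapse = ", "))
      }
    }
  }
  cohort
}

#' Serialize / load a statistical shape model
#'
#' JSON round trip preserving the mean shape, modes, eigenvalues, lattice
#' topology and training size exactly.
#'
#' @param model a `shape_model` from [fit_pca()].
#' @param path file path.
#' @export
serialize_shape_model <- function(model, path) {
  doc <- list(schema = "lv-shape-model-1",
              mean = model$mean, modes = unname(model$modes),
              eigenvalues = model$eigenvalues,
              n_retained = model$n_retained, n_train = model$n_train,
              n_circ = model$n_circ, n_long = model$n_long)
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              na = "null"), path)
  invisible(path)
}

#' @rdname serialize_shape_model
#' @export
read_shape_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (doc$schema != "lv-shape-model-1") stop("unrecognized shape-model schema")
  structure(list(mean = doc$mean, modes = doc$modes,
                 eigenvalues = doc$eigenvalues, n_retained = doc$n_retained,
                 n_train = doc$n_train, n_circ = doc$n_circ,
                 n_long = doc$n_long),
            class = "shape_model")
}

#' Serialize / load an LVAS model
#'
#' Round-trips the sparse Cox-Lasso weights, selected penalty, CV curve,
#' training normalization bounds and quartile cutpoints exactly, so a stored
#' model reproduces identical scores.
#'
#' @param model an `lvas_model` from [build_lvas()].
#' @param path file path.
#' @export
serialize_lvas <- function(model, path) {
  doc <- list(schema = "lvas-model-1",
              weights = model$weights,
              selected_mode_indices = model$selected_mode_indices,
              lambda_selected = model$lambda_selected,
              cv_lambda = model$cv_curve$lambda, cv_value = model$cv_curve$cvl,
              raw_score_min = model$raw_score_min,
              raw_score_max = model$raw_score_max,
              quartile_cutpoints = model$quartile_cutpoints)
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              na = "null"), path)
  invisible(path)
}

#' @rdname serialize_lvas
#' @export
read_lvas <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (doc$schema != "lvas-model-1") stop("unrecognized LVAS schema")
  structure(list(weights = doc$weights,
                 selected_mode_indices = doc$selected_mode_indices,
                 lambda_selected = doc$lambda_selected,
                 cv_curve = data.frame(lambda = doc$cv_lambda,
                                       cvl = doc$cv_value),
                 raw_score_min = doc$raw_score_min,
                 raw_score_max = doc$raw_score_max,
                 quartile_cutpoints = doc$quartile_cutpoints),
            class = "lvas_model")
}
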