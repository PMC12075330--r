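# Triangle-mesh kernel. Meshes are plain lists: vertices (n x 3 numeric,
# millimetres), faces (m x 3 integer, 1-based, consistent outward winding),
# name. All downstream geometry assumes watertight, outward-oriented input.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param name optional label carried through I/O and diagnostics.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a `tri_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Per-face vertex coordinate matrices (list of three m x 3 matrices).
face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1L], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2L], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3L], , drop = FALSE])
}

row_cross <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Face areas of a mesh
#' @param mesh a `tri_mesh`.
#' @return numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- row_cross(fc$b - fc$a, fc$c - fc$a)
  0.5 * sqrt(rowSums(cr * cr))
}

# Unit face normals (rows); zero rows for degenerate faces.
face_normals <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- row_cross(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(cr * cr))
  len[len == 0] <- 1
  cr / len
}

#' Signed volume of a watertight mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes over all triangles.
#' Positive for consistent outward orientation.
#'
#' @param mesh a `tri_mesh`; must be watertight and consistently oriented.
#' @param check if `TRUE` (default) error when boundary edges are present.
#' @return volume in mm^3.
#' @export
signed_volume <- function(mesh, check = TRUE) {
  if (check) {
    nb <- count_boundary_edges(mesh)
    if (nb > 0L) {
      stop(sprintf("mesh '%s' is not watertight: %d boundary edge(s)",
                   mesh$name, nb))
    }
  }
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * row_cross(fc$b, fc$c))) / 6
}

# Undirected edge keys as doubles (safe for < ~9e7 vertices).
edge_keys <- function(faces, n_vert) {
  i <- c(faces[, 1L], faces[, 2L], faces[, 3L])
  j <- c(faces[, 2L], faces[, 3L], faces[, 1L])
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * as.double(n_vert) + hi
}

count_boundary_edges <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0L)
  k <- edge_keys(mesh$faces, nrow(mesh$vertices))
  tab <- table(k)
  sum(tab == 1L)
}

#' Merge duplicate vertices
#'
#' Collapses vertices closer than `tol` (by coordinate rounding) and drops
#' faces that become degenerate. STL files store every triangle's corners
#' independently, so this is what turns a facet soup into a shared-vertex mesh.
#'
#' @param mesh a `tri_mesh`.
#' @param tol merge tolerance in mm.
#' @return a `tri_mesh` with unique vertices.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1L] / tol), round(v[, 2L] / tol),
               round(v[, 3L] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3L)
  keep <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
  tri_mesh(newv, f[keep, , drop = FALSE], mesh$name)
}

#' Reference distance for unit scaling
#'
#' Two marked points plus their true physical separation; used to scale a
#' unitless scan into millimetres, mirroring reference marks measured on the
#' physical model base.
#'
#' @param marker_a,marker_b length-3 numeric points on (or near) the mesh.
#' @param true_distance_mm known physical distance between the markers.
#' @return object of class `scale_reference`.
#' @export
scale_reference <- function(marker_a, marker_b, true_distance_mm) {
  marker_a <- as.numeric(marker_a)
  marker_b <- as.numeric(marker_b)
  if (length(marker_a) != 3L || length(marker_b) != 3L) {
    stop("markers must be 3D points")
  }
  if (!is.finite(true_distance_mm) || true_distance_mm <= 0) {
    stop("true_distance_mm must be positive")
  }
  structure(list(marker_a = marker_a, marker_b = marker_b,
                 true_distance_mm = true_distance_mm),
            class = "scale_reference")
}

#' Scale a mesh to physical units via reference markers
#'
#' Applies the uniform scale `s = true_distance_mm / |marker_a - marker_b|`
#' about the vertex centroid. Volume scales by `s^3`.
#'
#' @param mesh a `tri_mesh`.
#' @param ref a [scale_reference()].
#' @return the scaled `tri_mesh`.
#' @export
scale_to_reference <- function(mesh, ref) {
  stopifnot(inherits(ref, "scale_reference"))
  d <- sqrt(sum((ref$marker_a - ref$marker_b)^2))
  if (d < 1e-9) stop("degenerate scale reference: markers coincide")
  s <- ref$true_distance_mm / d
  ctr <- colMeans(mesh$vertices)
  v <- sweep(mesh$vertices, 2L, ctr)
  v <- v * s
  v <- sweep(v, 2L, ctr, `+`)
  tri_mesh(v, mesh$faces, mesh$name)
}

#' Flip the orientation of every face
#' @param mesh a `tri_mesh`.
#' @return mesh with reversed winding.
#' @export
reverse_orientation <- function(mesh) {
  tri_mesh(mesh$vertices, mesh$faces[, c(1L, 3L, 2L), drop = FALSE],
           mesh$name)
}

#' Axis frame of a tooth model
#'
#' Origin on the crown's longitudinal axis plus the occlusal direction
#' (unit vector; +z by package convention).
#'
#' @param origin length-3 point, reference level on the axis.
#' @param occlusal_dir length-3 direction pointing occlusally.
#' @return object of class `axis_frame`.
#' @export
axis_frame <- function(origin = c(0, 0, 0), occlusal_dir = c(0, 0, 1)) {
  occlusal_dir <- as.numeric(occlusal_dir)
  n <- sqrt(sum(occlusal_dir^2))
  if (n < 1e-12) stop("occlusal_dir must be non-zero")
  structure(list(origin = as.numeric(origin),
                 occlusal_dir = occlusal_dir / n),
            class = "axis_frame")
}

#' Bounding box of a mesh
#' @param mesh a `tri_mesh`.
#' @return 2 x 3 matrix, rows = min / max.
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2L, min),
        max = apply(mesh$vertices, 2L, max))
}

#' Translate a mesh
#' @param mesh a `tri_mesh`.
#' @param offset length-3 translation in mm.
#' @return translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  tri_mesh(sweep(mesh$vertices, 2L, as.numeric(offset), `+`),
           mesh$faces, mesh$name)
}
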