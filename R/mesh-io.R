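# STL / OBJ readers and writers. STL is accepted in both binary and ASCII
# form; OBJ is the documentation export format. Written by hand because the
# mesh kernel itself is part of this package.

is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  # A binary STL has exactly 84 + 50 * ntri bytes; ASCII files that happen to
  # start with "solid" fail this check.
  isTRUE(size == 84 + 50 * as.double(ntri))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (ntri <= 0L) stop("empty binary STL: ", path)
  rec <- readBin(con, "raw", 50L * ntri)
  idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L +
    rep(seq_len(48L), times = ntri)
  floats <- readBin(rec[idx], "numeric", n = 12L * ntri, size = 4L,
                    endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)
  verts <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                 m[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("not a valid ASCII STL (", length(vl), " vertex records): ", path)
  }
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[2:4])
  })
  verts <- do.call(rbind, nums)
  if (anyNA(verts)) stop("malformed vertex record in ", path)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Read an STL file
#'
#' Accepts binary and ASCII STL. Duplicate corner vertices are merged (the
#' format stores a facet soup), giving a shared-vertex mesh. Coordinates are
#' treated as unitless until [scale_to_reference()] is applied.
#'
#' @param path path to the STL file.
#' @param merge_tol vertex merge tolerance (mm), default 1e-6.
#' @param name label for the mesh; defaults to the file name.
#' @return a `tri_mesh`. If the merged mesh is non-manifold, a validation
#'   warning is attached as attribute `"validation"`.
#' @export
read_stl <- function(path, merge_tol = 1e-6, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0) stop("empty STL file: ", path)
  raw <- if (is_binary_stl(path)) read_stl_binary(path) else
    read_stl_ascii(path)
  mesh <- merge_vertices(tri_mesh(raw$vertices, raw$faces, name), merge_tol)
  nb <- count_boundary_edges(mesh)
  if (nb > 0L) {
    warning(sprintf("mesh '%s' has %d boundary edge(s) after merge", name, nb))
    attr(mesh, "validation") <- sprintf("%d boundary edges", nb)
  }
  mesh
}

#' Write a mesh as ASCII STL
#' @param mesh a `tri_mesh`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_stl <- function(mesh, path) {
  fc <- face_corners(mesh)
  n <- face_normals(mesh)
  m <- nrow(mesh$faces)
  fmt_pt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L])
  body <- character(7L * m)
  body[seq(1L, by = 7L, length.out = m)] <-
    paste0("  facet normal ", fmt_pt(n))
  body[seq(2L, by = 7L, length.out = m)] <- "    outer loop"
  body[seq(3L, by = 7L, length.out = m)] <- paste0("      vertex ", fmt_pt(fc$a))
  body[seq(4L, by = 7L, length.out = m)] <- paste0("      vertex ", fmt_pt(fc$b))
  body[seq(5L, by = 7L, length.out = m)] <- paste0("      vertex ", fmt_pt(fc$c))
  body[seq(6L, by = 7L, length.out = m)] <- "    endloop"
  body[seq(7L, by = 7L, length.out = m)] <- "  endfacet"
  writeLines(c(sprintf("solid %s", mesh$name), body,
               sprintf("endsolid %s", mesh$name)), path)
  invisible(path)
}

#' Write a mesh as Wavefront OBJ
#'
#' Plain v/f records at full double precision; reading the file back
#' round-trips vertices within 1e-6 mm.
#'
#' @param mesh a `tri_mesh`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", mesh$name), con)
  writeLines(sprintf("v %.12g %.12g %.12g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Read a Wavefront OBJ file
#'
#' Supports the v/f subset written by [write_obj()] (and slash-style face
#' records, taking the vertex index).
#'
#' @param path path to the OBJ file.
#' @param name label for the mesh.
#' @return a `tri_mesh`.
#' @export
read_obj <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) stop("no v/f records in ", path)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*$", "", x[2:4]))
  }))
  tri_mesh(verts, faces, name)
}

#' Write a CEJ (or margin) polyline sidecar file
#'
#' Plain text, one "x y z" triple per vertex; the curve is closed implicitly
#' (last vertex connects back to the first).
#'
#' @param curve numeric matrix (n x 3) of curve points.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cej_curve <- function(curve, path) {
  curve <- as.matrix(curve)
  writeLines(sprintf("%.9g %.9g %.9g",
                     curve[, 1L], curve[, 2L], curve[, 3L]), path)
  invisible(path)
}

#' Read a CEJ polyline sidecar file
#' @param path path to the plain-text curve file.
#' @return numeric matrix (n x 3).
#' @export
read_cej_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(read.table(path, col.names = c("x", "y", "z")))
  dimnames(m) <- NULL
  if (nrow(m) < 3L) stop("CEJ curve needs at least 3 points")
  m
}
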