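# Watertightness / manifoldness diagnostics. Boolean robustness downstream
# relies on every edge being shared by exactly two consistently wound faces.

# Vectorized segment-triangle intersection (Moller-Trumbore, strict interior,
# t strictly inside (eps, 1-eps)). All arguments are n x 3 matrices.
segments_hit_triangles <- function(p0, p1, a, b, c, eps = 1e-9) {
  d <- p1 - p0
  e1 <- b - a
  e2 <- c - a
  h <- row_cross(d, e2)
  det <- rowSums(e1 * h)
  ok <- abs(det) > eps
  det[!ok] <- 1
  inv <- 1 / det
  s <- p0 - a
  u <- rowSums(s * h) * inv
  q <- row_cross(s, e1)
  v <- rowSums(d * q) * inv
  t <- rowSums(e2 * q) * inv
  ok & u > eps & v > eps & (u + v) < 1 - eps & t > eps & t < 1 - eps
}

# Sampled self-intersection check: spatially binned candidate pairs that do
# not share a vertex, each tested edge-vs-triangle both ways.
sample_self_intersections <- function(mesh, max_pairs = 200000L) {
  nf <- nrow(mesh$faces)
  if (nf < 2L) return(0L)
  fc <- face_corners(mesh)
  ctr <- (fc$a + fc$b + fc$c) / 3
  ext <- pmax(
    apply(abs(fc$a - fc$b), 1L, max),
    apply(abs(fc$b - fc$c), 1L, max),
    apply(abs(fc$a - fc$c), 1L, max)
  )
  cell <- max(stats::quantile(ext, 0.9), 1e-6)
  # register every triangle in all grid cells its bounding box touches so
  # that nearby triangles always share a cell
  lo <- pmin(fc$a, fc$b, fc$c)
  hi <- pmax(fc$a, fc$b, fc$c)
  i0 <- floor(lo / cell)
  i1 <- floor(hi / cell)
  span <- as.integer((i1[, 1L] - i0[, 1L] + 1) * (i1[, 2L] - i0[, 2L] + 1) *
                       (i1[, 3L] - i0[, 3L] + 1))
  rec_tri <- rep.int(seq_len(nf), span)
  k <- sequence(span) - 1L
  wx <- (i1[, 1L] - i0[, 1L] + 1L)[rec_tri]
  wy <- (i1[, 2L] - i0[, 2L] + 1L)[rec_tri]
  dx <- k %% wx
  dy <- (k %/% wx) %% wy
  dz <- k %/% (wx * wy)
  key <- paste(i0[rec_tri, 1L] + dx, i0[rec_tri, 2L] + dy,
               i0[rec_tri, 3L] + dz)
  groups <- split(rec_tri, key)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (g in groups) {
    g <- unique(g)
    if (length(g) < 2L) next
    cmb <- utils::combn(g, 2L)
    pairs_i <- c(pairs_i, cmb[1L, ])
    pairs_j <- c(pairs_j, cmb[2L, ])
    if (length(pairs_i) > 4L * max_pairs) break
  }
  if (length(pairs_i) == 0L) return(0L)
  dup <- duplicated((pairs_i - 1) * as.double(nf) + pairs_j)
  pairs_i <- pairs_i[!dup]
  pairs_j <- pairs_j[!dup]
  if (length(pairs_i) > max_pairs) {
    keep <- seq_len(max_pairs)
    pairs_i <- pairs_i[keep]
    pairs_j <- pairs_j[keep]
  }
  f <- mesh$faces
  share <- (f[pairs_i, 1L] == f[pairs_j, 1L]) | (f[pairs_i, 1L] == f[pairs_j, 2L]) |
    (f[pairs_i, 1L] == f[pairs_j, 3L]) | (f[pairs_i, 2L] == f[pairs_j, 1L]) |
    (f[pairs_i, 2L] == f[pairs_j, 2L]) | (f[pairs_i, 2L] == f[pairs_j, 3L]) |
    (f[pairs_i, 3L] == f[pairs_j, 1L]) | (f[pairs_i, 3L] == f[pairs_j, 2L]) |
    (f[pairs_i, 3L] == f[pairs_j, 3L])
  pairs_i <- pairs_i[!share]
  pairs_j <- pairs_j[!share]
  if (length(pairs_i) == 0L) return(0L)
  hit <- rep(FALSE, length(pairs_i))
  corners <- list(fc$a, fc$b, fc$c)
  for (e in 1:3) {
    p0 <- corners[[e]]
    p1 <- corners[[e %% 3L + 1L]]
    hit <- hit | segments_hit_triangles(
      p0[pairs_i, , drop = FALSE], p1[pairs_i, , drop = FALSE],
      fc$a[pairs_j, , drop = FALSE], fc$b[pairs_j, , drop = FALSE],
      fc$c[pairs_j, , drop = FALSE])
    hit <- hit | segments_hit_triangles(
      p0[pairs_j, , drop = FALSE], p1[pairs_j, , drop = FALSE],
      fc$a[pairs_i, , drop = FALSE], fc$b[pairs_i, , drop = FALSE],
      fc$c[pairs_i, , drop = FALSE])
  }
  sum(hit)
}

#' Watertightness and manifoldness report
#'
#' Diagnoses boundary edges (edges used by a single face), non-manifold edges
#' (used by more than two faces), inconsistent winding (an undirected edge
#' traversed twice in the same direction), degenerate faces (area below
#' 1e-12 mm^2) and, optionally, a sampled triangle-triangle self-intersection
#' check. `pass` is `TRUE` iff all counts are zero.
#'
#' @param mesh a `tri_mesh`.
#' @param check_self_intersections run the (sampled) self-intersection test;
#'   default `FALSE` because it is the expensive part.
#' @return object of class `watertight_report` with fields
#'   `boundary_edges`, `nonmanifold_edges`, `misoriented_edges`,
#'   `degenerate_faces`, `self_intersections` (NA if not checked), `pass`.
#' @export
validate_watertight <- function(mesh, check_self_intersections = FALSE) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  i <- c(f[, 1L], f[, 2L], f[, 3L])
  j <- c(f[, 2L], f[, 3L], f[, 1L])
  undirected <- (pmin(i, j) - 1) * as.double(nv) + pmax(i, j)
  directed <- (i - 1) * as.double(nv) + j
  tab <- table(undirected)
  boundary <- sum(tab == 1L)
  nonmanifold <- sum(tab > 2L)
  # consistent winding: every directed edge appears exactly once
  misoriented <- sum(table(directed) > 1L)
  degenerate <- sum(face_areas(mesh) <= 1e-12)
  selfx <- if (check_self_intersections) {
    sample_self_intersections(mesh)
  } else NA_integer_
  pass <- boundary == 0L && nonmanifold == 0L && misoriented == 0L &&
    degenerate == 0L && (is.na(selfx) || selfx == 0L)
  structure(list(boundary_edges = boundary,
                 nonmanifold_edges = nonmanifold,
                 misoriented_edges = misoriented,
                 degenerate_faces = degenerate,
                 self_intersections = selfx,
                 pass = pass),
            class = "watertight_report")
}

#' @export
print.watertight_report <- function(x, ...) {
  cat(sprintf(paste0("watertight report: %s\n",
                     "  boundary edges:      %d\n",
                     "  non-manifold edges:  %d\n",
                     "  misoriented edges:   %d\n",
                     "  degenerate faces:    %d\n",
                     "  self-intersections:  %s\n"),
              if (x$pass) "PASS" else "FAIL",
              x$boundary_edges, x$nonmanifold_edges, x$misoriented_edges,
              x$degenerate_faces,
              if (is.na(x$self_intersections)) "not checked" else
                as.character(x$self_intersections)))
  invisible(x)
}
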