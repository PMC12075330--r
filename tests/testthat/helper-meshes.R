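# Shared geometric helpers and memoised fixtures for the test suite.

# unit cube [0, e]^3 as 12 triangles with consistent outward winding
cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge),
                             z = c(0, edge)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # y-z faces at x = 0? (fixed below by winding)
    c(2, 8, 4), c(2, 6, 8),
    c(1, 5, 6), c(1, 6, 2),
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),
    c(5, 7, 8), c(5, 8, 6))
  m <- tri_mesh(v, f, "cube")
  if (signed_volume(m, check = FALSE) < 0) m <- reverse_orientation(m)
  m
}

# icosphere: subdivided icosahedron projected to radius r
icosphere <- function(r = 1, subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    newv <- list()
    midpoint <- function(a, b) {
      key <- edge_id(a, b)
      id <- mids[[key]]
      if (is.null(id)) {
        newv[[length(newv) + 1L]] <<- (v[a, ] + v[b, ]) / 2
        id <- nv + length(newv)
        mids[[key]] <- id
      }
      id
    }
    nf <- list()
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[[length(nf) + 1L]] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- do.call(rbind, nf)
  }
  v <- v / sqrt(rowSums(v^2)) * r
  m <- tri_mesh(v, f, "icosphere")
  if (signed_volume(m, check = FALSE) < 0) m <- reverse_orientation(m)
  m
}

# ASCII STL text for a mesh, written independently of write_stl
ascii_stl_text <- function(mesh, name = "fixture") {
  fc <- list(a = mesh$vertices[mesh$faces[, 1L], , drop = FALSE],
             b = mesh$vertices[mesh$faces[, 2L], , drop = FALSE],
             c = mesh$vertices[mesh$faces[, 3L], , drop = FALSE])
  out <- c(sprintf("solid %s", name))
  for (i in seq_len(nrow(mesh$faces))) {
    out <- c(out, "facet normal 0 0 0", "outer loop",
             sprintf("vertex %.9g %.9g %.9g",
                     c(fc$a[i, 1], fc$b[i, 1], fc$c[i, 1]),
                     c(fc$a[i, 2], fc$b[i, 2], fc$c[i, 2]),
                     c(fc$a[i, 3], fc$b[i, 3], fc$c[i, 3])),
             "endloop", "endfacet")
  }
  c(out, sprintf("endsolid %s", name))
}

# closed-form removed vol% for a cylinder crown prepared with zero chamfer:
# cylinder below the margin plus a frustum tapering at the preparation angle
# up to the reduced flat top
cylinder_frustum_pct <- function(r, H, angle_deg, d, o) {
  a <- angle_deg * pi / 180
  hf <- (H - o) - d
  r2 <- r - hf * tan(a)
  stopifnot(hf > 0, r2 > 0)
  v_prep <- pi * r^2 * d + pi / 3 * hf * (r^2 + r * r2 + r2^2)
  100 * (pi * r^2 * H - v_prep) / (pi * r^2 * H)
}

# memoised fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

get_cylinder <- function() {
  if (is.null(.fixtures$cyl)) {
    .fixtures$cyl <- make_cylinder_tooth(5, 8)
  }
  .fixtures$cyl
}

get_molar_fast <- function() {
  if (is.null(.fixtures$molar)) {
    .fixtures$molar <- make_molar_like(
      tooth_spec(), resolution = mesh_resolution(preset = "fast"))
  }
  .fixtures$molar
}

run_removal <- function(tooth, angle, chamfer, d, o,
                        resolution = mesh_resolution(preset = "fast")) {
  prep <- suppressWarnings(apply_preparation(
    tooth, prep_params(angle, chamfer, d, o),
    resolution = resolution, crown_only = TRUE))
  removal_percent(tooth, prep)
}

# subgrid study over the molar fixture, shared by the acceptance tests
get_molar_subgrid <- function() {
  if (is.null(.fixtures$subgrid)) {
    grid <- study_grid(angle_deg = c(6, 10, 14),
                       chamfer_mm = c(0.2, 0.8, 1.6),
                       finish_line_mm = c(1, 3, 6),
                       occlusal_mm = c(0.5, 1.0, 1.5))
    .fixtures$subgrid <- run_factorial_study(get_molar_fast(), grid)
  }
  .fixtures$subgrid
}
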