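# Structured re-meshing of axis-star-shaped solids. A solid is described by
# boundary-fitted wall columns (matrices of z and radius per angular station,
# bottom ring to junction ring), a top-cap height field, and a bottom cap
# (flat disc or a fan blended through a non-planar curve such as the CEJ).
# The mesher emits a watertight, outward-oriented tri_mesh; every Boolean
# result in the package is produced this way from composed fields.

# Quad-strip triangles between consecutive rows of an (nr x nt) vertex grid,
# wrapping in theta. `ids` maps (row, station) -> vertex id.
strip_faces <- function(ids_a, ids_b) {
  nt <- length(ids_a)
  jp <- c(2:nt, 1L)
  rbind(cbind(ids_a, ids_a[jp], ids_b[jp]),
        cbind(ids_a, ids_b[jp], ids_b))
}

fan_faces <- function(ring_ids, center_id) {
  nt <- length(ring_ids)
  jp <- c(2:nt, 1L)
  cbind(ring_ids, ring_ids[jp], rep(center_id, nt))
}

#' Mesh resolution settings
#'
#' Controls the structured-grid density used when solids are re-meshed.
#' Defaults give sub-0.1% volume discretization error on the shipped
#' fixtures; `preset = "fast"` is used for large factorial sweeps.
#'
#' @param n_theta angular stations around the axis.
#' @param n_wall rows along the axial wall / preparation profile.
#' @param n_below rows between the CEJ and the preparation margin.
#' @param n_root rows along the root.
#' @param n_cap rings across the occlusal cap.
#' @param n_fan rings across the CEJ fan cap used for root removal.
#' @param preset `"default"` or `"fast"`; explicit arguments override.
#' @return a list of class `mesh_resolution`.
#' @export
mesh_resolution <- function(n_theta = NULL, n_wall = NULL, n_below = NULL,
                            n_root = NULL, n_cap = NULL, n_fan = NULL,
                            preset = c("default", "fast")) {
  preset <- match.arg(preset)
  base <- switch(preset,
    default = list(n_theta = 256L, n_wall = 72L, n_below = 24L,
                   n_root = 10L, n_cap = 44L, n_fan = 12L),
    fast = list(n_theta = 144L, n_wall = 48L, n_below = 14L,
                n_root = 8L, n_cap = 30L, n_fan = 10L))
  ov <- list(n_theta = n_theta, n_wall = n_wall, n_below = n_below,
             n_root = n_root, n_cap = n_cap, n_fan = n_fan)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) base[[nm]] <- as.integer(ov[[nm]])
  structure(base, class = "mesh_resolution")
}

# theta stations (no duplicated endpoint)
theta_stations <- function(nt) seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]

# Assemble a watertight solid.
#   theta   : nt angular stations
#   wall_z  : nr x nt z-coordinates, row 1 = bottom ring, row nr = junction
#   wall_r  : nr x nt radii (>= 0)
#   cap_fn  : function(x, y) -> z, the top height field
#   bottom  : list(kind = "disc") flat fan at the bottom ring's (constant) z,
#             or list(kind = "fan", z_curve = z per station) fan blended
#             through a closed non-planar bottom curve
#   n_cap, n_fan : ring counts for top cap / bottom fan
solid_from_columns <- function(theta, wall_z, wall_r, cap_fn, bottom,
                               n_cap = 40L, n_fan = 12L, name = "solid") {
  nt <- length(theta)
  nr <- nrow(wall_z)
  stopifnot(ncol(wall_z) == nt, all(dim(wall_r) == dim(wall_z)))
  ct <- cos(theta)
  st <- sin(theta)
  vx <- sweep(wall_r, 2L, ct, `*`)
  vy <- sweep(wall_r, 2L, st, `*`)
  verts <- cbind(as.vector(t(vx)), as.vector(t(vy)), as.vector(t(wall_z)))
  ids <- matrix(seq_len(nr * nt), nrow = nr, byrow = TRUE)
  faces <- vector("list", 8L)
  f_wall <- do.call(rbind, lapply(seq_len(nr - 1L), function(i) {
    strip_faces(ids[i, ], ids[i + 1L, ])
  }))
  faces[[1L]] <- f_wall
  # --- top cap ---
  rj <- wall_r[nr, ]
  s_cap <- seq(1, 0, length.out = n_cap + 2L)[-c(1L, n_cap + 2L)]
  cap_rows <- vector("list", length(s_cap))
  prev_ids <- ids[nr, ]
  next_id <- nr * nt
  f_cap <- vector("list", length(s_cap) + 1L)
  for (k in seq_along(s_cap)) {
    rr <- s_cap[k] * rj
    x <- rr * ct
    y <- rr * st
    zz <- cap_fn(x, y)
    cap_rows[[k]] <- cbind(x, y, zz)
    row_ids <- next_id + seq_len(nt)
    next_id <- next_id + nt
    f_cap[[k]] <- strip_faces(prev_ids, row_ids)
    prev_ids <- row_ids
  }
  center_top <- next_id + 1L
  f_cap[[length(s_cap) + 1L]] <- fan_faces(prev_ids, center_top)
  verts <- rbind(verts, do.call(rbind, cap_rows),
                 c(0, 0, cap_fn(0, 0)))
  faces[[2L]] <- do.call(rbind, f_cap)
  next_id <- center_top
  # --- bottom cap (normals point down: build inward rows, then flip) ---
  r0 <- wall_r[1L, ]
  if (identical(bottom$kind, "disc")) {
    zb <- wall_z[1L, ]
    zbar <- mean(zb)
    z_curve <- rep(zbar, nt)
  } else {
    z_curve <- bottom$z_curve
    zbar <- mean(z_curve)
  }
  s_fan <- seq(1, 0, length.out = n_fan + 2L)[-c(1L, n_fan + 2L)]
  fan_rows <- vector("list", length(s_fan))
  prev_ids <- ids[1L, ]
  f_bot <- vector("list", length(s_fan) + 1L)
  for (k in seq_along(s_fan)) {
    s <- s_fan[k]
    rr <- s * r0
    zz <- zbar + s * (z_curve - zbar)
    fan_rows[[k]] <- cbind(rr * ct, rr * st, zz)
    row_ids <- next_id + seq_len(nt)
    next_id <- next_id + nt
    f_bot[[k]] <- strip_faces(prev_ids, row_ids)
    prev_ids <- row_ids
  }
  center_bot <- next_id + 1L
  f_bot[[length(s_fan) + 1L]] <- fan_faces(prev_ids, center_bot)
  verts <- rbind(verts, do.call(rbind, fan_rows), c(0, 0, zbar))
  fb <- do.call(rbind, f_bot)
  faces[[3L]] <- fb[, c(1L, 3L, 2L), drop = FALSE]  # flip: outward = down
  mesh <- tri_mesh(verts, do.call(rbind, faces[1:3]), name)
  mesh
}

# March up wall columns to the first crossing with a height field.
# wall_fn(theta_idx_matrix, z_matrix) -> radius matrix; ladder is a list of
# per-station z ladders (m x nt). Returns list(z, r): junction per station.
solve_junction <- function(theta, ladder_z, ladder_r, height_fn,
                           refine = 18L) {
  nt <- length(theta)
  m <- nrow(ladder_z)
  ct <- rep(cos(theta), each = m)
  st <- rep(sin(theta), each = m)
  x <- as.vector(ladder_r) * ct
  y <- as.vector(ladder_r) * st
  g <- matrix(height_fn(x, y) - as.vector(ladder_z), nrow = m)
  below <- g <= 0
  # first ladder station at/below the height field
  first <- apply(below, 2L, function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_integer_ else w[1L]
  })
  if (anyNA(first)) {
    stop(sprintf("wall never meets the occlusal field at %d station(s); %s",
                 sum(is.na(first)),
                 "increase the wall extension or check the height field"))
  }
  if (any(first == 1L)) {
    stop(sprintf(
      "wall starts above the occlusal field at theta = %.3f rad",
      theta[which(first == 1L)[1L]]))
  }
  idx <- cbind(first - 1L, seq_len(nt))
  idx_hi <- cbind(first, seq_len(nt))
  g_lo <- g[idx]
  g_hi <- g[idx_hi]
  z_lo <- ladder_z[idx]
  z_hi <- ladder_z[idx_hi]
  r_lo <- ladder_r[idx]
  r_hi <- ladder_r[idx_hi]
  w <- g_lo / (g_lo - g_hi)
  w[!is.finite(w)] <- 0.5
  w <- pmin(pmax(w, 0), 1)
  list(z = z_lo + w * (z_hi - z_lo),
       r = r_lo + w * (r_hi - r_lo),
       i_lo = first - 1L)
}
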