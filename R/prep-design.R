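# Preparation design: chamfer finish-line profile, margin extraction, cutter
# solids, Boolean subtraction and seam smoothing. The axial cutter is the
# swept chamfer profile (hollow form enclosing the tooth silhouette); the
# occlusal cutter follows the tooth's own occlusal surface translated down
# the axis. Booleans compose the exact cutter fields with the tooth fields
# and re-mesh (see fields-mesher.R).

#' Preparation parameters
#'
#' The four parameters of a preparation design. The preparation angle is
#' half of the convergence angle: the axial wall's deviation from the
#' crown's longitudinal axis, converging occlusally.
#'
#' @param prep_angle_deg preparation angle in degrees, in `[0, 30)`.
#' @param chamfer_depth_mm radial width of the chamfer curvature (equal to
#'   the transition-arc radius), >= 0.
#' @param finish_line_distance_mm vertical distance of the margin above the
#'   CEJ, >= 0.
#' @param occlusal_reduction_mm vertical occlusal clearance, >= 0.
#' @return a list of class `prep_params`.
#' @export
prep_params <- function(prep_angle_deg, chamfer_depth_mm,
                        finish_line_distance_mm, occlusal_reduction_mm) {
  p <- list(prep_angle_deg = prep_angle_deg,
            chamfer_depth_mm = chamfer_depth_mm,
            finish_line_distance_mm = finish_line_distance_mm,
            occlusal_reduction_mm = occlusal_reduction_mm)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L)))) {
    stop("all preparation parameters must be finite scalars")
  }
  if (p$prep_angle_deg < 0 || p$prep_angle_deg >= 30) {
    stop("prep_angle_deg must lie in [0, 30)")
  }
  if (p$chamfer_depth_mm < 0) stop("chamfer_depth_mm must be >= 0")
  if (p$finish_line_distance_mm < 0) {
    stop("finish_line_distance_mm must be >= 0")
  }
  if (p$occlusal_reduction_mm < 0) stop("occlusal_reduction_mm must be >= 0")
  structure(p, class = "prep_params")
}

#' @export
print.prep_params <- function(x, ...) {
  cat(sprintf(
    "<prep_params: angle %g deg, chamfer %g mm, finish line %g mm, occlusal %g mm>\n",
    x$prep_angle_deg, x$chamfer_depth_mm, x$finish_line_distance_mm,
    x$occlusal_reduction_mm))
  invisible(x)
}

#' Build the chamfer finish-line profile
#'
#' The planar profile swept along the margin: a horizontal floor point at
#' the origin (the margin), a circular transition arc of radius
#' `chamfer_depth_mm` tangent to the horizontal at the origin, and an axial
#' wall line tangent to the arc, tilted `prep_angle_deg` from vertical with
#' the radius decreasing occlusally. Coordinates are (u = outward radial,
#' v = occlusal); the profile is C1-continuous and v is monotone along it.
#'
#' @param params a [prep_params()].
#' @param wall_height_mm height of the axial wall above the margin (must
#'   exceed the chamfer rise).
#' @param n_arc arc stations in the exported polyline.
#' @return object of class `chamfer_profile` with the polyline, the tangent
#'   point, and `u_of_v(v)`, the exact radial inset function.
#' @export
build_chamfer_profile <- function(params, wall_height_mm, n_arc = 32L) {
  stopifnot(inherits(params, "prep_params"))
  c0 <- params$chamfer_depth_mm
  alpha <- params$prep_angle_deg * pi / 180
  if (!is.finite(wall_height_mm) || wall_height_mm <= 0) {
    stop("wall_height_mm must be positive")
  }
  if (c0 >= wall_height_mm) {
    stop("chamfer_depth_mm must be smaller than the wall height")
  }
  phi_max <- pi / 2 - alpha
  v1 <- c0 * (1 - sin(alpha))   # chamfer rise at the tangent point
  u1 <- -c0 * cos(alpha)        # radial inset at the tangent point
  tan_a <- tan(alpha)
  u_of_v <- function(v) {
    v <- pmin(v, wall_height_mm)
    if (c0 > 0) {
      ifelse(v <= v1,
             -sqrt(pmax(v * (2 * c0 - v), 0)),
             u1 - (v - v1) * tan_a)
    } else {
      -v * tan_a
    }
  }
  if (c0 > 0) {
    phi <- seq(0, phi_max, length.out = n_arc + 1L)
    poly <- cbind(u = -c0 * sin(phi), v = c0 * (1 - cos(phi)))
  } else {
    poly <- cbind(u = 0, v = 0)
  }
  poly <- rbind(poly, c(u_of_v(wall_height_mm), wall_height_mm))
  structure(list(polyline = poly,
                 arc_radius_mm = c0,
                 wall_tilt_deg = params$prep_angle_deg,
                 arc_sweep_deg = phi_max * 180 / pi,
                 tangent_point = c(u1, v1),
                 wall_height_mm = wall_height_mm,
                 u_of_v = u_of_v),
            class = "chamfer_profile")
}

# periodic linear interpolation over theta stations [0, 2pi)
interp_periodic <- function(theta_grid, values, theta) {
  nt <- length(theta_grid)
  step <- 2 * pi / nt
  t <- (theta %% (2 * pi)) / step
  i0 <- floor(t)
  fr <- t - i0
  i0 <- as.integer(i0 %% nt) + 1L
  i1 <- i0 %% nt + 1L
  values[i0] * (1 - fr) + values[i1] * fr
}

#' Extract the preparation margin curve
#'
#' The finish line: at each angular station the margin sits
#' `finish_line_distance_mm` vertically above the CEJ (so it follows a
#' non-planar CEJ), on the tooth surface. `mode = "planar"` instead places
#' it at a constant height above the mean CEJ level.
#'
#' @param tooth a `tooth_model`.
#' @param finish_line_distance_mm vertical margin offset above the CEJ (mm).
#' @param n_stations number of angular stations (uniform, default 360).
#' @param mode `"follow_cej"` (default) or `"planar"`.
#' @return object of class `margin_curve`: theta, rho, z, points (n x 3).
#' @export
extract_margin_curve <- function(tooth, finish_line_distance_mm,
                                 n_stations = 360L,
                                 mode = c("follow_cej", "planar")) {
  stopifnot(inherits(tooth, "tooth_model"))
  mode <- match.arg(mode)
  d <- finish_line_distance_mm
  if (!is.finite(d) || d < 0) {
    stop("finish_line_distance_mm must be >= 0")
  }
  theta <- theta_stations(n_stations)
  zc <- tooth$fields$z_cej(theta)
  z_m <- if (mode == "follow_cej") zc + d else mean(zc) + d
  jz <- interp_periodic(tooth$junction$theta, tooth$junction$z, theta)
  bad <- z_m > jz - 0.05
  if (any(bad)) {
    stop(sprintf(
      "margin lies above the occlusal surface at theta = %.3f rad (z = %.2f, surface %.2f)",
      theta[which(bad)[1L]], z_m[which(bad)[1L]], jz[which(bad)[1L]]))
  }
  rho <- tooth$fields$radial(theta, z_m)
  structure(list(theta = theta, rho = rho, z = z_m,
                 points = cbind(rho * cos(theta), rho * sin(theta), z_m),
                 finish_line_distance_mm = d, mode = mode),
            class = "margin_curve")
}

# exact inner-radius field of the axial cutter: +Inf below the margin floor,
# margin radius plus the profile inset above it
axial_cutter_field <- function(profile, margin) {
  th_grid <- margin$theta
  rho_m <- margin$rho
  z_grid <- margin$z
  u_of_v <- profile$u_of_v
  function(theta, z) {
    zm <- interp_periodic(th_grid, z_grid, theta)
    rm <- interp_periodic(th_grid, rho_m, theta)
    v <- z - zm
    ifelse(v < 0, Inf, rm + u_of_v(pmax(v, 0)))
  }
}

# closed "torus" mesh: rows form a closed loop in cross-section, swept in
# theta. rows_r, rows_z are nr x nt; consecutive rows (wrapping) are
# stitched with quad strips.
torus_from_rows <- function(theta, rows_r, rows_z, name) {
  nt <- length(theta)
  nr <- nrow(rows_r)
  ct <- cos(theta)
  st <- sin(theta)
  verts <- cbind(as.vector(t(sweep(rows_r, 2L, ct, `*`))),
                 as.vector(t(sweep(rows_r, 2L, st, `*`))),
                 as.vector(t(rows_z)))
  ids <- matrix(seq_len(nr * nt), nrow = nr, byrow = TRUE)
  faces <- do.call(rbind, lapply(seq_len(nr), function(i) {
    strip_faces(ids[i, ], ids[i %% nr + 1L, ])
  }))
  mesh <- merge_vertices(tri_mesh(verts, faces, name), tol = 1e-9)
  if (signed_volume(mesh, check = FALSE) < 0) mesh <- reverse_orientation(mesh)
  mesh
}

#' Sweep the chamfer profile along the margin into the axial cutter solid
#'
#' The hollow cutter whose inner boundary is the swept profile surface
#' (chamfer floor plus tapered axial wall, profile origin on each margin
#' point, u-axis along the outward radial direction) and whose outer
#' boundary is a cylinder strictly containing the tooth; closed below the
#' margin floor and above the apex. Subtracting it leaves the prepared
#' axial form.
#'
#' @param tooth a `tooth_model`.
#' @param profile a `chamfer_profile`.
#' @param margin a `margin_curve`.
#' @param n_rows rows along the profile in the cutter mesh.
#' @return object of class `cutter_solid` (fields `mesh`, `kind`, and the
#'   exact inner-radius field `inner_radius(theta, z)`).
#' @export
sweep_cutter <- function(tooth, profile, margin, n_rows = 48L) {
  stopifnot(inherits(tooth, "tooth_model"), inherits(profile, "chamfer_profile"),
            inherits(margin, "margin_curve"))
  theta <- margin$theta
  nt <- length(theta)
  z_top <- max(tooth$junction$z) + 1.0
  r_out <- max(tooth$fields$cej_rho(theta)) + 2.0
  vmax <- z_top - margin$z
  if (any(vmax <= profile$tangent_point[2L])) {
    stop("wall top must lie above the chamfer rise everywhere")
  }
  # inner wall rows: arc stations (theta-independent v), then wall stations
  n_arc <- max(8L, n_rows %/% 3L)
  n_wall <- n_rows - n_arc
  c0 <- profile$arc_radius_mm
  v_arc <- if (c0 > 0) {
    c0 * (1 - cos(seq(0, pi / 2 - profile$wall_tilt_deg * pi / 180,
                      length.out = n_arc + 1L)))
  } else rep(0, n_arc + 1L)
  v_inner <- rbind(matrix(v_arc[-(n_arc + 1L)], n_arc, nt),
                   outer(seq(0, 1, length.out = n_wall + 1L),
                         vmax - v_arc[n_arc + 1L]) + v_arc[n_arc + 1L])
  z_inner <- sweep(v_inner, 2L, margin$z, `+`)
  r_inner <- sweep(matrix(profile$u_of_v(as.vector(v_inner)),
                          nrow = nrow(v_inner)), 2L, margin$rho, `+`)
  if (min(r_inner) <= 0.05) {
    stop("profile inset exceeds the local radius: cutter wall pinches the axis")
  }
  n_ann <- 4L
  s_ann <- seq(0, 1, length.out = n_ann + 1L)[-1L]
  # top annulus: inner wall top -> outer cylinder at z_top
  r_topwall <- r_inner[nrow(r_inner), ]
  top_r <- outer(s_ann, r_out - r_topwall) + matrix(r_topwall, n_ann, nt,
                                                    byrow = TRUE)
  top_z <- matrix(z_top, n_ann, nt)
  # outer wall: z_top down to the margin floor level
  out_z <- outer(rev(s_ann), margin$z - z_top) + z_top
  out_r <- matrix(r_out, n_ann, nt)
  # bottom annulus: outer cylinder back inward to the margin point
  bot_r <- outer(rev(s_ann)[-1L], margin$rho - r_out) + r_out
  bot_z <- matrix(margin$z, n_ann - 1L, nt, byrow = TRUE)
  rows_r <- rbind(r_inner, top_r, out_r, bot_r)
  rows_z <- rbind(z_inner, top_z, out_z, bot_z)
  mesh <- torus_from_rows(theta, rows_r, rows_z,
                          name = "axial_cutter")
  structure(list(mesh = mesh, kind = "axial",
                 inner_radius = axial_cutter_field(profile, margin),
                 profile = profile, margin = margin,
                 z_top = z_top, r_out = r_out),
            class = "cutter_solid")
}

#' @export
print.cutter_solid <- function(x, ...) {
  cat(sprintf("<cutter_solid '%s': %d faces>\n", x$kind, nrow(x$mesh$faces)))
  invisible(x)
}

# Occlusal lower-boundary field: the tooth's occlusal surface translated by
# -reduction along the axis, with the translation blending to zero within
# blend_width (3D distance) of the margin curve - the gradual smoothing
# toward the outer cusp areas that keeps the finish line intact - and
# Laplacian smoothing of the blended surface. Smoothing strength scales
# with the reduction so a null reduction leaves the surface untouched.
# Outside the margin silhouette the field continues radially at its
# silhouette value (the cutter skirt cuts nothing the axial cutter has not
# already removed). Returns list(fn = closure(x, y), grid provenance).
occlusal_field <- function(tooth, margin, reduction, blend_width = 0.8,
                           n_s = 52L, lambda = 0.5, iterations = 8L) {
  theta <- margin$theta
  nt <- length(theta)
  s <- seq(0, 1.3, length.out = n_s)
  in_sil <- s <= 1
  n_in <- sum(in_sil)
  rho_sil <- margin$rho
  rr <- outer(s, rho_sil)
  x <- sweep(rr, 2L, cos(theta), `*`)
  y <- sweep(rr, 2L, sin(theta), `*`)
  # the translated surface is the occlusal *table* field; the steep axial
  # shoulder belongs to the axial cutter, and the cap respects the wall
  # envelope separately (see apply_preparation's h_cap)
  H <- matrix(tooth$fields$height(as.vector(x), as.vector(y)), nrow = n_s)
  # blend factor: 3D distance from each node, placed at its true surface
  # height, to the margin curve, scanned over nearby angular stations
  sfn <- if (is.null(tooth$fields$surface_z)) tooth$fields$height else
    tooth$fields$surface_z
  Hs <- matrix(sfn(as.vector(x), as.vector(y)), nrow = n_s)
  beta <- matrix(1, n_s, nt)
  mp <- margin$points
  for (dk in -4:4) {
    jj <- (seq_len(nt) - 1L + dk) %% nt + 1L
    d2 <- (x - matrix(mp[jj, 1L], n_s, nt, byrow = TRUE))^2 +
      (y - matrix(mp[jj, 2L], n_s, nt, byrow = TRUE))^2 +
      (Hs - matrix(mp[jj, 3L], n_s, nt, byrow = TRUE))^2
    beta <- pmin(beta, d2 / blend_width^2)
  }
  beta <- pmin(sqrt(beta), 1)
  M <- H - reduction * beta
  # radial continuation beyond the silhouette
  M[!in_sil, ] <- rep(M[n_in, ], each = n_s - n_in)
  lam <- lambda * min(1, reduction / 0.5)
  if (lam > 0 && iterations > 0L) {
    w <- beta
    w[s >= 1, ] <- 0
    for (it in seq_len(iterations)) {
      up <- M[c(1L, seq_len(n_s - 1L)), ]
      dn <- M[c(seq_len(n_s - 1L) + 1L, n_s), ]
      lf <- M[, c(nt, seq_len(nt - 1L))]
      rt <- M[, c(seq_len(nt - 1L) + 1L, 1L)]
      M <- M + lam * w * ((up + dn + lf + rt) / 4 - M)
      M[1L, ] <- mean(M[1L, ])  # the s = 0 row is a single point
    }
  }
  step <- 2 * pi / nt
  fn <- function(px, py) {
    th <- (atan2(py, px) %% (2 * pi)) / step
    i0 <- as.integer(floor(th)) %% nt + 1L
    fr <- th - floor(th)
    i1 <- i0 %% nt + 1L
    rs <- rho_sil[i0] * (1 - fr) + rho_sil[i1] * fr
    sv <- pmin(sqrt(px^2 + py^2) / rs, 1.3 - 1e-9) / (1.3 / (n_s - 1L))
    k0 <- as.integer(floor(sv)) + 1L
    fs <- sv - floor(sv)
    k1 <- pmin(k0 + 1L, n_s)
    M[cbind(k0, i0)] * (1 - fs) * (1 - fr) +
      M[cbind(k0, i1)] * (1 - fs) * fr +
      M[cbind(k1, i0)] * fs * (1 - fr) +
      M[cbind(k1, i1)] * fs * fr
  }
  list(fn = fn, grid = M, s = s, theta = theta, lambda_used = lam,
       iterations = iterations, blend_width_mm = blend_width)
}

#' Build the occlusal reduction cutter
#'
#' A solid whose lower boundary is the tooth's own occlusal surface
#' translated down the axis by the occlusal reduction (anatomic reduction:
#' uniform vertical clearance), with gradual smoothing toward the outer cusp
#' areas; it extends above the apex and outward past the silhouette.
#'
#' @param tooth a `tooth_model`.
#' @param params a [prep_params()].
#' @param margin a `margin_curve` (for the silhouette blend); defaults to
#'   the margin at the params' finish-line distance.
#' @param blend_width_mm smoothing-weight decay width near the margin
#'   silhouette (mm).
#' @return a `cutter_solid` of kind `"occlusal"` (field `lower_z(x, y)`).
#' @export
build_occlusal_cutter <- function(tooth, params, margin = NULL,
                                  blend_width_mm = 0.8) {
  stopifnot(inherits(tooth, "tooth_model"), inherits(params, "prep_params"))
  red <- params$occlusal_reduction_mm
  if (is.null(margin)) {
    margin <- extract_margin_curve(tooth, params$finish_line_distance_mm,
                                   n_stations = tooth$resolution$n_theta)
  }
  jz <- interp_periodic(tooth$junction$theta, tooth$junction$z, margin$theta)
  if (red >= max(jz) - min(margin$z)) {
    stop("occlusal reduction exceeds the crown height above the margin")
  }
  of <- occlusal_field(tooth, margin, red, blend_width = blend_width_mm)
  # mesh the slab { lower(x,y) <= z <= z_top } over a disc by building it
  # upside-down with the generic mesher, then mirroring
  theta <- margin$theta
  nt <- length(theta)
  z_top <- max(tooth$junction$z) + 1.5
  r_out <- max(tooth$fields$cej_rho(theta)) + 2.0
  # rim heights evaluated at the y-mirrored stations used by the flipped build
  lower_rim <- of$fn(r_out * cos(theta), -r_out * sin(theta))
  nr <- 6L
  wall_z <- outer(seq(0, 1, length.out = nr), -lower_rim + z_top) - z_top
  wall_r <- matrix(r_out, nr, nt)
  flip_fn <- function(x, y) -of$fn(x, -y)  # mirror y to keep orientation
  m <- solid_from_columns(theta, wall_z, wall_r, flip_fn,
                          bottom = list(kind = "disc"),
                          n_cap = 40L, n_fan = 6L, name = "occlusal_cutter")
  v <- m$vertices
  v[, 2L] <- -v[, 2L]
  v[, 3L] <- -v[, 3L]
  mesh <- tri_mesh(v, m$faces, "occlusal_cutter")
  if (signed_volume(mesh, check = FALSE) < 0) mesh <- reverse_orientation(mesh)
  structure(list(mesh = mesh, kind = "occlusal", lower_z = of$fn,
                 field = of, z_top = z_top, r_out = r_out),
            class = "cutter_solid")
}

#' Apply a preparation design to a tooth
#'
#' Full Boolean pipeline: extract the margin, build the chamfer profile and
#' the axial cutter, subtract it, subtract the occlusal cutter, then smooth
#' the Boolean seams. Subtraction composes the exact cutter fields with the
#' tooth fields (axial: pointwise minimum of radius fields above the margin
#' floor; occlusal: minimum of height fields) and re-meshes the result on a
#' boundary-fitted grid, so the chamfer arc is resolved by construction.
#'
#' @param tooth a `tooth_model`.
#' @param params a [prep_params()].
#' @param resolution a [mesh_resolution()]; defaults to the tooth's.
#' @param smoothing a [smoothing_settings()]; `iterations = 0` disables
#'   seam smoothing.
#' @param smoothing_guard maximum |volume change| from smoothing, as a
#'   fraction of the removed volume (default 0.005).
#' @param crown_only if `TRUE`, skip the full (rooted) mesh and produce the
#'   crown mesh only (the study fast path; vol%% never involves the root).
#' @param keep_cutters if `TRUE`, attach the cutter solids (meshes included)
#'   to the result for export / inspection.
#' @return object of class `prepared_tooth`: `mesh` (full prepared tooth,
#'   `NULL` when `crown_only`), `crown_mesh`, `params`, and `provenance`
#'   (fixture id, smoothing settings and volume delta, margin and profile).
#' @export
apply_preparation <- function(tooth, params,
                              resolution = NULL,
                              smoothing = smoothing_settings(),
                              smoothing_guard = 0.005,
                              crown_only = FALSE,
                              keep_cutters = FALSE) {
  stopifnot(inherits(tooth, "tooth_model"), inherits(params, "prep_params"))
  res <- if (is.null(resolution)) tooth$resolution else resolution
  nt <- res$n_theta
  theta <- theta_stations(nt)
  margin <- extract_margin_curve(tooth, params$finish_line_distance_mm,
                                 n_stations = nt)
  z_top <- max(tooth$junction$z) + 1.5
  wall_height <- z_top - min(margin$z)
  profile <- build_chamfer_profile(params, wall_height)
  r_cut <- axial_cutter_field(profile, margin)
  occ <- occlusal_field(tooth, margin, params$occlusal_reduction_mm)
  # two height criteria: the junction march asks where the wall meets the
  # occlusal table (or its reduction); the cap surface additionally respects
  # the tooth's wall envelope so it can follow a remaining shoulder
  h_table <- tooth$fields$height
  h_jn <- function(x, y) pmin(h_table(x, y), occ$fn(x, y))
  h_tooth <- if (is.null(tooth$fields$surface_z)) tooth$fields$height else
    tooth$fields$surface_z
  h_cap <- function(x, y) pmin(h_tooth(x, y), occ$fn(x, y))
  zc <- tooth$fields$z_cej(theta)
  if (h_jn(0, 0) <= mean(zc) + 0.2) {
    stop("occlusal reduction consumes the crown down to the CEJ")
  }
  # --- preparation wall ladder: arc stations + wall stations per theta ---
  c0 <- params$chamfer_depth_mm
  alpha <- params$prep_angle_deg * pi / 180
  n_arc_l <- 44L
  n_wall_l <- 110L
  v1 <- c0 * (1 - sin(alpha))
  v_arc <- if (c0 > 0) {
    c0 * (1 - cos(seq(0, pi / 2 - alpha, length.out = n_arc_l + 1L)))
  } else seq(0, 0, length.out = n_arc_l + 1L)
  vmax <- z_top - margin$z
  # combined wall ladder: tooth surface CEJ -> margin (section A), then the
  # profile path margin -> wall top (section B). The junction with the
  # occlusal field may fall in either section: a tall finish line combined
  # with an anatomic occlusal offset legitimately truncates the wall below
  # the margin.
  n_al <- 36L
  a_z <- outer(seq(0, 1, length.out = n_al), margin$z - zc) +
    matrix(zc, n_al, nt, byrow = TRUE)
  a_r <- matrix(tooth$fields$radial(rep(theta, each = n_al),
                                    as.vector(a_z)), nrow = n_al)
  b_v <- rbind(matrix(v_arc, n_arc_l + 1L, nt),
               outer(seq(0, 1, length.out = n_wall_l)[-1L],
                     vmax - v_arc[n_arc_l + 1L]) + v_arc[n_arc_l + 1L])
  b_z <- sweep(b_v, 2L, margin$z, `+`)
  b_rc <- sweep(matrix(profile$u_of_v(as.vector(b_v)),
                       nrow = nrow(b_v)), 2L, margin$rho, `+`)
  b_rt <- matrix(tooth$fields$radial(rep(theta, each = nrow(b_z)),
                                     as.vector(b_z)), nrow = nrow(b_z))
  b_r_raw <- pmin(b_rc, b_rt)
  lad_z <- rbind(a_z[-n_al, , drop = FALSE], b_z)
  lad_r_raw <- rbind(a_r[-n_al, , drop = FALSE], b_r_raw)
  lad_r <- pmax(lad_r_raw, 1e-4)
  jn <- solve_junction(theta, lad_z, lad_r, h_jn)
  # pinch check only below the junction: above it the wall is cut away
  used <- row(lad_r_raw) <= matrix(jn$i_lo + 1L, nrow(lad_r_raw),
                                   nt, byrow = TRUE)
  if (min(lad_r_raw[used]) <= 1e-4) {
    stop("profile inset exceeds the local radius: cutter wall pinches the axis")
  }
  # resample each station's wall path onto the fixed row budget:
  # n_below + 1 rows CEJ -> margin plus n_wall rows margin -> junction when
  # the junction sits above the margin; otherwise all rows span the
  # truncated path CEJ -> junction.
  n_wall <- res$n_wall
  n_below <- res$n_below
  n_rows <- n_below + 1L + n_wall
  crown_z <- matrix(0, n_rows, nt)
  crown_r <- matrix(0, n_rows, nt)
  resample_path <- function(zs, rs, n_out) {
    cl <- cumsum(c(0, sqrt(diff(zs)^2 + diff(rs)^2)))
    keep <- !duplicated(cl)
    if (cl[length(cl)] < 1e-9) {
      return(list(z = rep(zs[length(zs)], n_out), r = rep(rs[length(rs)], n_out)))
    }
    tgt <- seq(0, cl[length(cl)], length.out = n_out)
    list(z = approx(cl[keep], zs[keep], xout = tgt)$y,
         r = approx(cl[keep], rs[keep], xout = tgt)$y)
  }
  for (j in seq_len(nt)) {
    kj <- jn$i_lo[j]
    if (jn$z[j] > margin$z[j] + 1e-9) {
      # section B junction: exact margin breakpoint, profile-fitted rows
      fr <- seq(0, 1, length.out = n_below + 1L)
      crown_z[seq_len(n_below + 1L), j] <- zc[j] + fr * (margin$z[j] - zc[j])
      crown_r[seq_len(n_below + 1L), j] <-
        tooth$fields$radial(rep(theta[j], n_below + 1L),
                            zc[j] + fr * (margin$z[j] - zc[j]))
      crown_r[n_below + 1L, j] <- margin$rho[j]
      kb <- kj - (n_al - 1L)          # index into section B ladder
      kb <- max(kb, 1L)
      zs <- c(b_z[seq_len(kb), j], jn$z[j])
      rs <- c(pmax(b_r_raw[seq_len(kb), j], 1e-4), jn$r[j])
      rp <- resample_path(zs, rs, n_wall + 1L)
      crown_z[n_below + 1L + seq_len(n_wall), j] <- rp$z[-1L]
      crown_r[n_below + 1L + seq_len(n_wall), j] <- rp$r[-1L]
    } else {
      # junction below the margin: occlusal field truncates the intact wall
      zs <- c(a_z[seq_len(min(kj, n_al - 1L)), j], jn$z[j])
      rs <- c(a_r[seq_len(min(kj, n_al - 1L)), j], jn$r[j])
      rp <- resample_path(zs, rs, n_rows)
      crown_z[, j] <- rp$z
      crown_r[, j] <- rp$r
    }
  }
  crown_z[1L, ] <- zc
  crown_r[1L, ] <- tooth$fields$radial(theta, zc)
  crown <- solid_from_columns(theta, crown_z, crown_r, h_cap,
                              bottom = list(kind = "fan", z_curve = zc),
                              n_cap = res$n_cap, n_fan = res$n_fan,
                              name = paste0(tooth$fixture_id, "_prepared_crown"))
  removed_est <- tooth$crown_volume_mm3 - signed_volume(crown, check = FALSE)
  guard <- max(smoothing_guard * max(removed_est, 0), 1e-9)
  crown_s <- smooth_seams(crown, settings = smoothing, max_delta_mm3 = guard)
  sm <- attr(crown_s, "smoothing")
  full <- NULL
  if (!crown_only) {
    n_root <- res$n_root
    z_bot <- tooth$fields$z_bottom
    fr_root <- seq(0, 1, length.out = n_root + 1L)[seq_len(n_root)]
    root_z <- outer(fr_root, zc - z_bot) + z_bot
    root_r <- matrix(tooth$fields$radial(rep(theta, each = n_root),
                                         as.vector(root_z)),
                     nrow = n_root)
    root_z[1L, ] <- z_bot
    full <- solid_from_columns(theta, rbind(root_z, crown_z),
                               rbind(root_r, crown_r), h_cap,
                               bottom = list(kind = "disc"),
                               n_cap = res$n_cap, n_fan = res$n_fan,
                               name = paste0(tooth$fixture_id, "_prepared"))
    full <- smooth_seams(full, settings = smoothing, max_delta_mm3 = guard)
  }
  out <- list(mesh = full,
              crown_mesh = crown_s,
              params = params,
              cej_curve = tooth$cej_curve,
              provenance = list(
                fixture_id = tooth$fixture_id,
                smoothing = smoothing,
                smoothing_delta_mm3 = sm$delta_mm3,
                smoothing_iterations_used = sm$iterations_used,
                removed_est_mm3 = removed_est,
                margin = margin,
                profile = profile,
                occlusal = occ[c("lambda_used", "iterations",
                                 "blend_width_mm")],
                resolution = res))
  if (keep_cutters) {
    out$cutters <- list(
      axial = sweep_cutter(tooth, profile, margin),
      occlusal = build_occlusal_cutter(tooth, params, margin))
  }
  structure(out, class = "prepared_tooth")
}

#' @export
print.prepared_tooth <- function(x, ...) {
  cat(sprintf(
    "<prepared_tooth from '%s': angle %g deg, chamfer %g mm, finish line %g mm, occlusal %g mm>\n",
    x$provenance$fixture_id, x$params$prep_angle_deg,
    x$params$chamfer_depth_mm, x$params$finish_line_distance_mm,
    x$params$occlusal_reduction_mm))
  invisible(x)
}
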