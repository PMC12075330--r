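# Synthetic tooth fixtures. Each tooth model carries, besides its watertight
# mesh and annotated CEJ curve, the implicit fields that define the solid:
# a lateral radius field R(theta, z) about the occlusal (+z) axis and an
# occlusal height field H(x, y). The solid is
#   { rho <= R(theta, z) }  ∩  { z <= H(x, y) }  ∩  { z >= bottom }.
# Preparation Booleans compose these fields and re-mesh.

#' Synthetic molar specification
#'
#' Shape parameters for the molar-like fixture: a superellipse-like crown
#' cross-section tapering occlusally, an occlusal table with Gaussian cusp
#' bumps and a central fossa, a cosine-wave (non-planar) CEJ, and a simple
#' frustum root. Identical spec + seed always yields an identical mesh.
#'
#' @param crown_height_mm CEJ-to-occlusal-table height (mm).
#' @param cej_radius_mm crown radius at the CEJ in the cardinal directions.
#' @param cross_section_exponent superellipse exponent (2 = circular,
#'   larger = squarer).
#' @param cusp_count number of cusps on the occlusal table.
#' @param cusp_height_mm cusp bump height (mm); 0 removes cusps and fossa.
#' @param cusp_sigma_mm Gaussian bump width (mm).
#' @param cej_wave_amp_mm amplitude of the non-planar CEJ wave (mm).
#' @param cej_wave_lobes integer number of CEJ wave lobes.
#' @param root_length_mm root frustum length below the CEJ (mm).
#' @param seed integer; deterministically jitters cusp placement.
#' @return a list of class `tooth_spec`.
#' @export
tooth_spec <- function(crown_height_mm = 7.5, cej_radius_mm = 5.5,
                       cross_section_exponent = 2.05, cusp_count = 4L,
                       cusp_height_mm = 1.5, cusp_sigma_mm = 1.15,
                       cej_wave_amp_mm = 1.0, cej_wave_lobes = 2L,
                       root_length_mm = 8.0, seed = 42L) {
  spec <- list(crown_height_mm = crown_height_mm,
               cej_radius_mm = cej_radius_mm,
               cross_section_exponent = cross_section_exponent,
               cusp_count = as.integer(cusp_count),
               cusp_height_mm = cusp_height_mm,
               cusp_sigma_mm = cusp_sigma_mm,
               cej_wave_amp_mm = cej_wave_amp_mm,
               cej_wave_lobes = as.integer(cej_wave_lobes),
               root_length_mm = root_length_mm,
               seed = as.integer(seed))
  if (spec$crown_height_mm <= 0) stop("crown_height_mm must be > 0")
  if (spec$cej_radius_mm <= 0) stop("cej_radius_mm must be > 0")
  if (spec$cross_section_exponent < 2) {
    stop("cross_section_exponent must be >= 2")
  }
  if (spec$cusp_height_mm < 0) stop("cusp_height_mm must be >= 0")
  if (spec$cusp_count > 0L && spec$cusp_sigma_mm <= 0) {
    stop("cusp_sigma_mm must be > 0")
  }
  if (spec$cej_wave_amp_mm < 0) stop("cej_wave_amp_mm must be >= 0")
  if (spec$root_length_mm <= 0) stop("root_length_mm must be > 0")
  structure(spec, class = "tooth_spec")
}

#' Read / write a tooth spec as YAML
#' @param path file path.
#' @return for `read_tooth_spec`, a `tooth_spec`.
#' @export
read_tooth_spec <- function(path) {
  do.call(tooth_spec, yaml::read_yaml(path))
}

#' @rdname read_tooth_spec
#' @param spec a `tooth_spec`.
#' @export
write_tooth_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

# superellipse base radius at angle theta
superellipse_radius <- function(theta, a, n) {
  a * (abs(cos(theta))^n + abs(sin(theta))^n)^(-1 / n)
}

# Shared tooth-model builder. `fields` is a list with vectorized closures:
#   radial(theta, z), height(x, y), z_cej(theta), cej_rho(theta)
# plus z_bottom and u_max (ladder extension above the crown, in units of
# crown height).
build_tooth_model <- function(fields, crown_height, resolution, name,
                              spec = NULL) {
  res <- resolution
  nt <- res$n_theta
  theta <- theta_stations(nt)
  zc <- fields$z_cej(theta)
  # ladder along the lateral field, CEJ upward, for the junction solve
  m <- 220L
  u <- seq(0.005, fields$u_max, length.out = m)
  ladder_z <- outer(u * crown_height, zc, `+`)
  ladder_r <- matrix(
    fields$radial(rep(theta, each = m), as.vector(ladder_z)), nrow = m)
  if (!is.null(fields$junction_z_vec)) {
    # pre-computed junction heights (mesh-derived teeth: the junction is
    # where the lateral ray-cast data ends and the vertical data takes over)
    jz <- fields$junction_z_vec
    stopifnot(length(jz) == nt)
    jn <- list(z = jz, r = fields$radial(theta, jz))
  } else {
    h_jn <- if (is.null(fields$height_for_junction)) fields$height else
      fields$height_for_junction
    jn <- solve_junction(theta, ladder_z, ladder_r, h_jn)
  }
  # wall-envelope surface: at plan point (theta, rho) the largest z with
  # lateral radius >= rho. The tooth's true surface height is the minimum of
  # the occlusal table field and this envelope; preparations whose margin or
  # cap reach the occlusal shoulder need it.
  n_env <- 192L
  Mdesc <- apply(ladder_r, 2L, function(col) rev(cummax(rev(col))))
  rho_top <- Mdesc[1L, ]
  env_z <- matrix(0, n_env, nt)
  se <- seq(1e-6, 1, length.out = n_env)
  for (j in seq_len(nt)) {
    xr <- rev(Mdesc[, j])
    xr <- cummax(xr) + 1e-9 * seq_along(xr)
    yr <- rev(ladder_z[, j])
    env_z[, j] <- approx(xr, yr, xout = se * rho_top[j], rule = 2L)$y
  }
  step_t <- 2 * pi / nt
  env_fn <- function(px, py) {
    ti <- (atan2(py, px) %% (2 * pi)) / step_t
    i0 <- as.integer(floor(ti)) %% nt + 1L
    frt <- ti - floor(ti)
    i1 <- i0 %% nt + 1L
    rt <- rho_top[i0] * (1 - frt) + rho_top[i1] * frt
    sv <- pmin(sqrt(px^2 + py^2) / rt, 1 - 1e-9) / (1 / (n_env - 1L))
    # conservative in rho: take the inner (upper) grid value - the envelope
    # inverse is near-vertical at flat radius maxima and must never be
    # under-estimated, or walls graze their own envelope
    k0 <- as.integer(floor(sv)) + 1L
    env_z[cbind(k0, i0)] * (1 - frt) + env_z[cbind(k0, i1)] * frt
  }
  # small upward bias keeps the envelope from grazing its own wall
  fields$surface_z <- local({
    h <- fields$height
    function(px, py) pmin(h(px, py), env_fn(px, py) + 0.05)
  })
  n_crown <- res$n_below + res$n_wall
  fr <- seq(0, 1, length.out = n_crown + 1L)
  crown_z <- outer(fr, jn$z - zc) + matrix(zc, n_crown + 1L, nt, byrow = TRUE)
  crown_r <- matrix(
    fields$radial(rep(theta, each = n_crown + 1L), as.vector(crown_z)),
    nrow = n_crown + 1L)
  crown_z[n_crown + 1L, ] <- jn$z
  crown_r[n_crown + 1L, ] <- jn$r
  # full tooth: root rows below the CEJ, flat disc at the root tip
  n_root <- res$n_root
  z_bot <- fields$z_bottom
  fr_root <- seq(0, 1, length.out = n_root + 1L)[seq_len(n_root)]
  root_z <- outer(fr_root, zc - z_bot) + z_bot
  root_r <- matrix(
    fields$radial(rep(theta, each = n_root), as.vector(root_z)),
    nrow = n_root)
  full_z <- rbind(root_z, crown_z)
  full_r <- rbind(root_r, crown_r)
  full_z[1L, ] <- z_bot
  mesh <- solid_from_columns(theta, full_z, full_r, fields$height,
                             bottom = list(kind = "disc"),
                             n_cap = res$n_cap, n_fan = res$n_fan,
                             name = name)
  crown <- solid_from_columns(theta, crown_z, crown_r, fields$height,
                              bottom = list(kind = "fan", z_curve = zc),
                              n_cap = res$n_cap, n_fan = res$n_fan,
                              name = paste0(name, "_crown"))
  rho_cej <- fields$cej_rho(theta)
  cej_curve <- cbind(rho_cej * cos(theta), rho_cej * sin(theta), zc)
  structure(list(mesh = mesh,
                 crown_mesh = crown,
                 axis = axis_frame(),
                 cej_curve = cej_curve,
                 crown_volume_mm3 = signed_volume(crown, check = FALSE),
                 fields = fields,
                 crown_height_mm = crown_height,
                 junction = list(theta = theta, z = jn$z, r = jn$r),
                 fixture_id = name,
                 spec = spec,
                 resolution = res),
            class = "tooth_model")
}

#' @export
print.tooth_model <- function(x, ...) {
  cat(sprintf(
    "<tooth_model '%s': crown %.1f mm3, %d faces, CEJ amp %.2f mm>\n",
    x$fixture_id, x$crown_volume_mm3, nrow(x$mesh$faces),
    diff(range(x$cej_curve[, 3L])) / 2))
  invisible(x)
}

#' Analytic cylinder tooth fixture
#'
#' Right circular cylinder crown with a flat occlusal cap, planar CEJ circle
#' at z = 0 and a frustum root. Crown volume is pi r^2 h in closed form,
#' which makes this the oracle fixture for volume and Boolean tests.
#'
#' @param radius_mm crown radius (mm).
#' @param crown_height_mm crown height above the CEJ (mm).
#' @param root_length_mm root length below the CEJ (mm).
#' @param resolution a [mesh_resolution()].
#' @return a `tooth_model`.
#' @export
make_cylinder_tooth <- function(radius_mm, crown_height_mm,
                                root_length_mm = 8,
                                resolution = mesh_resolution()) {
  if (!all(is.finite(c(radius_mm, crown_height_mm, root_length_mm))) ||
      radius_mm <= 0 || crown_height_mm <= 0 || root_length_mm <= 0) {
    stop("cylinder dimensions must be positive")
  }
  r <- radius_mm
  H <- crown_height_mm
  rl <- root_length_mm
  fields <- list(
    radial = function(theta, z) {
      w <- pmax(-z, 0) / rl
      r * (1 - 0.5 * pmin(w, 1))
    },
    height = function(x, y) rep(H, length(x)),
    z_cej = function(theta) rep(0, length(theta)),
    cej_rho = function(theta) rep(r, length(theta)),
    z_bottom = -rl,
    u_max = 1.35)
  build_tooth_model(fields, H, resolution,
                    name = sprintf("cylinder_r%g_h%g", r, H))
}

#' Synthetic molar-like tooth fixture
#'
#' Watertight stand-in for a scanned maxillary molar: superellipse-like
#' cross-section tapering occlusally, occlusal table with Gaussian cusps and
#' a central fossa, cosine-wave non-planar CEJ, frustum root. All shape
#' constants are documented package choices within published molar anatomy
#' ranges, not anatomical claims. Deterministic per (spec, seed).
#'
#' @param spec a [tooth_spec()].
#' @param resolution a [mesh_resolution()].
#' @return a `tooth_model`.
#' @export
make_molar_like <- function(spec = tooth_spec(),
                            resolution = mesh_resolution()) {
  stopifnot(inherits(spec, "tooth_spec"))
  a <- spec$cej_radius_mm
  n <- spec$cross_section_exponent
  ch <- spec$crown_height_mm
  amp <- spec$cej_wave_amp_mm
  lobes <- spec$cej_wave_lobes
  rl <- spec$root_length_mm
  # crown shape constants (validated at build time): near-vertical axial
  # walls with a slight cervical bulge (height of contour) and a gentle
  # overall convergence, closed occlusally by a high sculpted table - deep
  # central fossa, Gaussian cusps - so preparation walls stay in tooth
  # contact over their whole height, as on a posterior crown
  bulge_mm <- 0.03
  tip_drop <- 0.12
  p_out <- 8
  fossa_depth <- 1.5 * spec$cusp_height_mm
  sigma_fossa <- 0.55
  nc <- spec$cusp_count
  if (nc > 0L) {
    jit <- withr::with_seed(spec$seed, runif(3L * nc, -1, 1))
    cusp_amp <- spec$cusp_height_mm * (1 + 0.12 * jit[seq_len(nc)])
    cusp_ang <- pi / nc + (seq_len(nc) - 1L) * 2 * pi / nc +
      0.06 * jit[nc + seq_len(nc)]
    cusp_rad <- 0.55 + 0.03 * jit[2L * nc + seq_len(nc)]
    cusp_sig <- spec$cusp_sigma_mm / a
  } else {
    cusp_amp <- numeric(0)
  }
  z_cej <- function(theta) amp * cos(lobes * theta)
  base_r <- function(theta) superellipse_radius(theta, a, n)
  # lateral slope stays below tan(6 deg) everywhere so the shallowest
  # preparation wall remains in tooth contact up to the occlusal table
  lin_taper <- 0.105
  radial <- function(theta, z) {
    r0 <- base_r(theta)
    zc <- z_cej(theta)
    u <- (z - zc) / ch
    uc <- pmin(pmax(u, 0), 1.3)
    crown <- r0 * (1 - lin_taper * uc) +
      bulge_mm * sin(pi * pmin(pmax(u, 0), 1))
    w <- pmin(pmax(-u * ch / rl, 0), 1)
    ifelse(u >= 0, crown, r0 * (1 - 0.55 * w))
  }
  height <- function(x, y) {
    th <- atan2(y, x)
    rho_hat <- sqrt(x^2 + y^2) / base_r(th)
    # the CEJ-wave offset fades quadratically toward the axis so the table
    # stays smooth at the center while the occlusal third still follows the
    # CEJ wave (keeps tall finish lines feasible at every station)
    wave <- z_cej(th) * pmin(rho_hat, 1.2)^2
    # tip falloff saturates at the silhouette: beyond it the field only has
    # to stay below the wall, not plunge
    tt <- ch * (1 - tip_drop * pmin(rho_hat, 1)^p_out) -
      fossa_depth * exp(-rho_hat^2 / (2 * sigma_fossa^2))
    if (length(cusp_amp) > 0L) {
      px <- rho_hat * cos(th)
      py <- rho_hat * sin(th)
      for (k in seq_along(cusp_amp)) {
        d2 <- (px - cusp_rad[k] * cos(cusp_ang[k]))^2 +
          (py - cusp_rad[k] * sin(cusp_ang[k]))^2
        tt <- tt + cusp_amp[k] * exp(-d2 / (2 * cusp_sig^2))
      }
    }
    wave + tt
  }
  fields <- list(radial = radial, height = height, z_cej = z_cej,
                 cej_rho = base_r, z_bottom = -amp - rl, u_max = 1.35)
  model <- build_tooth_model(fields, ch, resolution,
                             name = sprintf("molar_seed%d", spec$seed),
                             spec = spec)
  # cap-slope guard: the occlusal field must not outrun the steepest wall
  # taper, otherwise the wall/cap split is ambiguous
  check_cap_slope(model, max_slope = 1 / tan(16 * pi / 180))
  model
}

# numeric guard: max |dH/d rho| over the cap region
check_cap_slope <- function(model, max_slope) {
  th <- theta_stations(64L)
  s <- seq(0.05, 0.95, length.out = 40L)
  rj <- approx(c(model$junction$theta, 2 * pi),
               c(model$junction$r, model$junction$r[1L]),
               xout = th)$y
  rr <- outer(s, rj)
  x <- sweep(rr, 2L, cos(th), `*`)
  y <- sweep(rr, 2L, sin(th), `*`)
  h <- 1e-3
  gx <- (model$fields$height(as.vector(x) + h, as.vector(y)) -
           model$fields$height(as.vector(x) - h, as.vector(y))) / (2 * h)
  gy <- (model$fields$height(as.vector(x), as.vector(y) + h) -
           model$fields$height(as.vector(x), as.vector(y) - h)) / (2 * h)
  slope <- max(sqrt(gx^2 + gy^2))
  if (slope > max_slope) {
    stop(sprintf(
      "occlusal field slope %.2f exceeds the wall-compatibility bound %.2f",
      slope, max_slope))
  }
  invisible(slope)
}

#' Crown-only region of a tooth model
#'
#' The tooth cut by the standardized CEJ cap surface (see [cut_root()]);
#' its volume is the denominator of all vol% results.
#'
#' @param tooth a `tooth_model`.
#' @return a watertight `tri_mesh` of the crown.
#' @export
crown_region <- function(tooth) {
  stopifnot(inherits(tooth, "tooth_model"))
  tooth$crown_mesh
}

#' Built-in fixture catalog
#'
#' @param name `"molar"` (default molar-like spec) or `"cylinder"`
#'   (r = 5 mm, crown 8 mm).
#' @param resolution a [mesh_resolution()].
#' @return a `tooth_model`.
#' @export
fixture_tooth <- function(name = c("molar", "cylinder"),
                          resolution = mesh_resolution()) {
  name <- match.arg(name)
  switch(name,
         molar = make_molar_like(tooth_spec(), resolution),
         cylinder = make_cylinder_tooth(5, 8, resolution = resolution))
}
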