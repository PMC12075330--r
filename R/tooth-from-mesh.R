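# Tooth models from external meshes (e.g. a scanned tooth loaded from STL).
# The lateral radius and occlusal height fields are recovered by ray casting
# the actual triangles on a cylindrical grid; the model is then re-meshed on
# the package's structured grid, which is what every preparation Boolean
# operates on. Requires the crown to be star-shaped about the occlusal axis
# (the same requirement the margin sweep imposes).

# periodic resampling of a closed curve onto uniform theta stations
resample_curve_theta <- function(curve, theta) {
  th <- atan2(curve[, 2L], curve[, 1L])
  o <- order(th)
  th <- th[o]
  rho <- sqrt(curve[o, 1L]^2 + curve[o, 2L]^2)
  z <- curve[o, 3L]
  th_ext <- c(th - 2 * pi, th, th + 2 * pi)
  tq <- atan2(sin(theta), cos(theta))
  list(rho = approx(th_ext, rep(rho, 3L), xout = tq)$y,
       z = approx(th_ext, rep(z, 3L), xout = tq)$y)
}

# fill NA runs in a column: interior by interpolation, tails by nearest /
# linear extrapolation of the last two finite values (floored)
fill_column <- function(zs, vals, floor_val = 0.02) {
  ok <- is.finite(vals)
  if (!any(ok)) return(rep(floor_val, length(vals)))
  if (all(ok)) return(vals)
  out <- approx(zs[ok], vals[ok], xout = zs, rule = 2L)$y
  # extrapolate the upper tail with the last finite slope (tapering crown)
  iok <- which(ok)
  top <- iok[length(iok)]
  if (top < length(vals) && length(iok) >= 2L) {
    i2 <- iok[length(iok) - 1L]
    slope <- (vals[top] - vals[i2]) / (zs[top] - zs[i2])
    idx <- (top + 1L):length(vals)
    out[idx] <- pmax(vals[top] + slope * (zs[idx] - zs[top]), floor_val)
  }
  out
}

#' Build a tooth model from a mesh and an annotated CEJ curve
#'
#' Recovers the lateral radius field (horizontal rays from the axis) and
#' the occlusal height field (vertical rays) from the triangle mesh, then
#' re-meshes the solid on the structured grid used by the preparation
#' pipeline. The mesh must be watertight, in mm (see
#' [scale_to_reference()]), oriented with +z occlusal, and star-shaped
#' about the z-axis.
#'
#' @param mesh a watertight `tri_mesh`.
#' @param cej_curve closed CEJ polyline (n x 3) on the mesh surface.
#' @param resolution a [mesh_resolution()].
#' @param name fixture label.
#' @return a `tooth_model`.
#' @export
tooth_from_mesh <- function(mesh, cej_curve,
                            resolution = mesh_resolution(),
                            name = mesh$name) {
  stopifnot(inherits(mesh, "tri_mesh"))
  curve <- validate_cej_curve(cej_curve)
  nt <- resolution$n_theta
  theta <- theta_stations(nt)
  cej <- resample_curve_theta(curve, theta)
  bb <- mesh_bbox(mesh)
  zmin <- bb[1L, 3L]
  zmax <- bb[2L, 3L]
  nz <- max(120L, min(480L, as.integer(ceiling((zmax - zmin) / 0.04))))
  zg <- seq(zmin + 1e-4, zmax - 1e-4, length.out = nz)
  R <- matrix(mesh_radial_field(mesh, rep(theta, each = nz),
                                rep(zg, times = nt)), nrow = nz)
  # junction per station: one grid step below the last height at which the
  # horizontal ray still crosses the surface (above it the crown has turned
  # over into the occlusal table and vertical rays take over)
  junction_z <- vapply(seq_len(nt), function(j) {
    ok <- which(is.finite(R[, j]))
    if (length(ok) == 0L) stop("radial field empty at a station")
    zg[max(ok[length(ok)] - 1L, 1L)]
  }, numeric(1L))
  for (j in seq_len(nt)) R[, j] <- fill_column(zg, R[, j])
  rho_sil <- apply(R, 2L, max)
  ns <- 48L
  s <- seq(0, 1.05, length.out = ns)
  rr <- outer(s, rho_sil)
  hx <- sweep(rr, 2L, cos(theta), `*`)
  hy <- sweep(rr, 2L, sin(theta), `*`)
  H <- matrix(mesh_height_field(mesh, as.vector(hx), as.vector(hy)),
              nrow = ns)
  for (j in seq_len(nt)) {
    ok <- is.finite(H[, j])
    if (!any(ok)) stop("height field empty at a station; mesh not star-shaped?")
    H[, j] <- approx(s[ok], H[ok, j], xout = s, rule = 2L)$y
  }
  step <- 2 * pi / nt
  zstep <- zg[2L] - zg[1L]
  radial <- function(th, z) {
    ti <- (th %% (2 * pi)) / step
    i0 <- as.integer(floor(ti)) %% nt + 1L
    fr <- ti - floor(ti)
    i1 <- i0 %% nt + 1L
    zi <- pmin(pmax((z - zg[1L]) / zstep, 0), nz - 1L - 1e-9)
    k0 <- as.integer(floor(zi)) + 1L
    fz <- zi - floor(zi)
    k1 <- pmin(k0 + 1L, nz)
    R[cbind(k0, i0)] * (1 - fz) * (1 - fr) + R[cbind(k0, i1)] * (1 - fz) * fr +
      R[cbind(k1, i0)] * fz * (1 - fr) + R[cbind(k1, i1)] * fz * fr
  }
  height <- function(px, py) {
    ti <- (atan2(py, px) %% (2 * pi)) / step
    i0 <- as.integer(floor(ti)) %% nt + 1L
    fr <- ti - floor(ti)
    i1 <- i0 %% nt + 1L
    rs <- rho_sil[i0] * (1 - fr) + rho_sil[i1] * fr
    sv <- pmin(sqrt(px^2 + py^2) / rs, 1.05 - 1e-9) / (1.05 / (ns - 1L))
    k0 <- as.integer(floor(sv)) + 1L
    fs <- sv - floor(sv)
    k1 <- pmin(k0 + 1L, ns)
    H[cbind(k0, i0)] * (1 - fs) * (1 - fr) + H[cbind(k0, i1)] * (1 - fs) * fr +
      H[cbind(k1, i0)] * fs * (1 - fr) + H[cbind(k1, i1)] * fs * fr
  }
  z_cej_fn <- local({
    zc <- cej$z
    function(th) interp_periodic(theta, zc, th)
  })
  cej_rho_fn <- local({
    rc <- cej$rho
    function(th) interp_periodic(theta, rc, th)
  })
  crown_height <- max(H) - mean(cej$z)
  # the ray-cast height field is the true surface height, so along the wall
  # it grazes the wall itself; the junction march therefore asks for the
  # height slightly inside the local radius (plus a small bias), which
  # crosses only where the surface turns over into the occlusal table
  fields <- list(radial = radial, height = height,
                 junction_z_vec = junction_z, z_cej = z_cej_fn,
                 cej_rho = cej_rho_fn, z_bottom = zmin + 1e-3,
                 u_max = min(1.35, (zmax - min(cej$z) + 0.05) / crown_height))
  build_tooth_model(fields, crown_height, resolution, name = name)
}
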