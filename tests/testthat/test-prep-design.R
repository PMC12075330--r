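test_that("chamfer profile satisfies the circle tangency geometry", {
  # zero angle: quarter-circle arc from the margin to a vertical wall
  p0 <- build_chamfer_profile(prep_params(0, 0.5, 2, 0.5), wall_height_mm = 6)
  expect_equal(p0$arc_sweep_deg, 90)
  expect_equal(p0$tangent_point, c(-0.5, 0.5), tolerance = 1e-12)
  expect_equal(p0$u_of_v(0.25), -sqrt(0.25 * (1 - 0.25)), tolerance = 1e-12)
  expect_equal(p0$u_of_v(3), -0.5, tolerance = 1e-12)  # vertical wall
  # zero chamfer: a straight line tilted by the preparation angle
  p1 <- build_chamfer_profile(prep_params(10, 0, 2, 0.5), wall_height_mm = 6)
  v <- c(0.5, 1, 3)
  expect_equal(p1$u_of_v(v), -v * tan(10 * pi / 180), tolerance = 1e-12)
  # 8 degrees: arc sweep 82 degrees; tangent point from circle tangency
  # (independently: center (0, c), tangency = center + c * (-cos a, -sin a))
  a <- 8 * pi / 180
  p2 <- build_chamfer_profile(prep_params(8, 0.5, 2, 0.5), wall_height_mm = 6)
  expect_equal(p2$arc_sweep_deg, 82)
  expect_equal(p2$tangent_point,
               c(0, 0.5) + 0.5 * c(-cos(a), -sin(a)), tolerance = 1e-12)
  # v must be monotone along the polyline
  expect_true(all(diff(p2$polyline[, "v"]) >= 0))
  expect_error(build_chamfer_profile(prep_params(8, 2, 2, 0.5),
                                     wall_height_mm = 1.5), "smaller")
})

test_that("preparation parameters are validated", {
  expect_error(prep_params(-1, 0.5, 2, 0.5), "prep_angle")
  expect_error(prep_params(30, 0.5, 2, 0.5), "prep_angle")
  expect_error(prep_params(8, -0.1, 2, 0.5), "chamfer")
  expect_error(prep_params(8, 0.5, -1, 0.5), "finish_line")
  expect_error(prep_params(8, 0.5, 2, NA), "finite")
})

test_that("margin extraction follows the CEJ and rejects infeasible lines", {
  cyl <- get_cylinder()
  m <- extract_margin_curve(cyl, 2, n_stations = 90L)
  expect_equal(m$z, rep(2, 90L))
  expect_equal(m$rho, rep(5, 90L), tolerance = 1e-9)
  mol <- get_molar_fast()
  m2 <- extract_margin_curve(mol, 3, n_stations = 16L)
  # non-planar CEJ with amplitude 1 and two lobes: z = cos(2 theta) + 3
  expect_equal(m2$z, cos(2 * m2$theta) + 3, tolerance = 1e-9)
  on_surface <- mol$fields$radial(m2$theta, m2$z)
  expect_equal(m2$rho, on_surface, tolerance = 1e-9)
  expect_error(extract_margin_curve(cyl, 20), "above the occlusal")
})

test_that("swept axial cutter is watertight and hollow", {
  cyl <- get_cylinder()
  margin <- extract_margin_curve(cyl, 2, n_stations = 144L)
  profile <- build_chamfer_profile(prep_params(8, 0.6, 2, 0.5),
                                   wall_height_mm = max(cyl$junction$z) +
                                     1 - min(margin$z))
  cutter <- sweep_cutter(cyl, profile, margin)
  expect_s3_class(cutter, "cutter_solid")
  expect_identical(cutter$kind, "axial")
  expect_true(validate_watertight(cutter$mesh)$pass)
  # hollow form: the tooth axis region is outside the cutter
  axis_pts <- cbind(0, 0, seq(3, 7, length.out = 5))
  expect_false(any(point_in_mesh(cutter$mesh, axis_pts)))
  # the inner wall field reproduces the profile inset
  expect_equal(cutter$inner_radius(0, 2.0), 5, tolerance = 1e-6)
  expect_equal(cutter$inner_radius(0, 5.0),
               5 + profile$u_of_v(3), tolerance = 1e-6)
  expect_equal(cutter$inner_radius(0, 1.0), Inf)
})

test_that("null preparation removes (almost) nothing", {
  cyl <- get_cylinder()
  r0 <- run_removal(cyl, 0, 0, 2, 0)
  expect_lt(abs(r0$removed_pct), 0.1)
})

test_that("cylinder preparations match the frustum closed form", {
  cyl <- get_cylinder()
  r <- run_removal(cyl, 8, 0, 1, 1)
  expect_equal(r$removed_pct, cylinder_frustum_pct(5, 8, 8, 1, 1),
               tolerance = 0.5, ignore_attr = TRUE)
  expect_true(validate_watertight(
    suppressWarnings(apply_preparation(cyl, prep_params(8, 0, 1, 1),
                                       crown_only = TRUE))$crown_mesh)$pass)
})

test_that("chamfer-only removal matches the revolved-profile quadrature", {
  cyl <- get_cylinder()
  r <- run_removal(cyl, 0, 0.5, 2, 0)
  # independent 1D quadrature of the revolved chamfer profile
  zz <- seq(2, 8, length.out = 20001L)
  v <- zz - 2
  u <- ifelse(v <= 0.5, -sqrt(pmax(v * (1 - v), 0)), -0.5)
  v_above <- sum(pi * (5 + u)^2) * (zz[2L] - zz[1L])
  expected <- 100 * (pi * 25 * 6 - v_above) / (pi * 25 * 8)
  expect_equal(r$removed_pct, expected, tolerance = 0.05)
})

test_that("occlusal reduction gives the closed-form slab on a flat top", {
  cyl <- get_cylinder()
  r0 <- run_removal(cyl, 0, 0, 2, 0)
  r1 <- run_removal(cyl, 0, 0, 2, 1)
  slab <- r1$removed_mm3 - r0$removed_mm3
  expect_equal(slab, pi * 25 * 1, tolerance = 0.5)
  cutter <- build_occlusal_cutter(cyl, prep_params(0, 0, 2, 1))
  expect_identical(cutter$kind, "occlusal")
  expect_true(validate_watertight(cutter$mesh)$pass)
  expect_equal(cutter$lower_z(0, 0), 7, tolerance = 1e-6)
  expect_error(build_occlusal_cutter(cyl, prep_params(0, 0, 2, 20)),
               "reduction exceeds")
})

test_that("prepared solid excludes the cutter interior", {
  cyl <- get_cylinder()
  params <- prep_params(8, 0.6, 2, 1)
  prep <- suppressWarnings(apply_preparation(cyl, params, crown_only = TRUE,
                                             keep_cutters = TRUE))
  bb <- mesh_bbox(prep$crown_mesh)
  set.seed(11)
  pts <- cbind(runif(4000, bb[1, 1], bb[2, 1]),
               runif(4000, bb[1, 2], bb[2, 2]),
               runif(4000, bb[1, 3], bb[2, 3]))
  inside_prep <- point_in_mesh(prep$crown_mesh, pts)
  in_axial <- point_in_mesh(prep$cutters$axial$mesh, pts)
  in_occl <- point_in_mesh(prep$cutters$occlusal$mesh, pts)
  # Boolean validity: prepared points lie in neither cutter (allow a whisker
  # of surface-classification noise)
  expect_lt(mean(inside_prep & (in_axial | in_occl)), 0.005)
})

test_that("molar preparation agrees with the voxel oracle", {
  mol <- get_molar_fast()
  prep <- suppressWarnings(apply_preparation(
    mol, prep_params(8, 1.0, 4, 1.0), crown_only = TRUE))
  expect_true(validate_watertight(prep$crown_mesh)$pass)
  mesh_pct <- removal_percent(mol, prep)$removed_pct
  vox_pct <- voxel_oracle_percent(mol, prep, voxel_mm = 0.1)
  expect_equal(mesh_pct, vox_pct, tolerance = 1, ignore_attr = TRUE)
})

test_that("removal responds monotonically on the cylinder oracle", {
  cyl <- get_cylinder()
  base <- run_removal(cyl, 8, 0.4, 2, 1)$removed_pct
  expect_gt(run_removal(cyl, 12, 0.4, 2, 1)$removed_pct, base)
  expect_gt(run_removal(cyl, 8, 0.8, 2, 1)$removed_pct, base)
  expect_gt(run_removal(cyl, 8, 0.4, 1, 1)$removed_pct, base)
  expect_gt(run_removal(cyl, 8, 0.4, 2, 1.5)$removed_pct, base)
})
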