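test_that("cylinder fixture has closed-form crown volume and CEJ circle", {
  cyl <- get_cylinder()
  expect_equal(cyl$crown_volume_mm3, pi * 25 * 8, tolerance = 1e-3)
  expect_true(validate_watertight(cyl$mesh)$pass)
  expect_true(validate_watertight(cyl$crown_mesh)$pass)
  cej <- cyl$cej_curve
  expect_equal(max(abs(cej[, 3])), 0, tolerance = 1e-9)
  expect_equal(sqrt(cej[, 1]^2 + cej[, 2]^2), rep(5, nrow(cej)),
               tolerance = 1e-9)
  expect_error(make_cylinder_tooth(0, 8), "positive")
  expect_error(make_cylinder_tooth(5, -1), "positive")
})

test_that("molar fixture is watertight, in its volume band, deterministic", {
  mol <- get_molar_fast()
  expect_true(validate_watertight(mol$mesh)$pass)
  expect_true(validate_watertight(mol$crown_mesh)$pass)
  # sanity band checked with the independent voxel oracle
  vox <- voxel_volume(mol$crown_mesh, 0.15)
  expect_gt(vox, 200)
  expect_lt(vox, 600)
  expect_equal(vox, mol$crown_volume_mm3, tolerance = 0.01)
  mol2 <- make_molar_like(tooth_spec(),
                          resolution = mesh_resolution(preset = "fast"))
  expect_identical(mol$mesh$vertices, mol2$mesh$vertices)
  mol3 <- make_molar_like(tooth_spec(seed = 7L),
                          resolution = mesh_resolution(preset = "fast"))
  expect_false(identical(mol$mesh$vertices, mol3$mesh$vertices))
})

test_that("degenerate molar matches a solid-of-revolution quadrature", {
  spec <- tooth_spec(cusp_height_mm = 0, cej_wave_amp_mm = 0,
                     cross_section_exponent = 2)
  mol <- make_molar_like(spec, resolution = mesh_resolution(preset = "fast"))
  # axisymmetric solid: integrate pi * rho_max(z)^2 over the crown, where
  # rho_max is the smaller of the lateral radius and the radius at which
  # the occlusal table drops to z
  zg <- seq(1e-4, max(mol$junction$z) + 2, length.out = 4000L)
  r_lat <- mol$fields$radial(rep(0, length(zg)), zg)
  rho_cap <- vapply(zg, function(z) {
    f <- function(rho) mol$fields$height(rho, 0) - z
    if (f(1e-6) <= 0) return(0)
    if (f(r_lat[1]) >= 0) return(Inf)
    stats::uniroot(f, c(1e-6, r_lat[1]))$root
  }, numeric(1L))
  rho <- pmin(r_lat, rho_cap)
  v_quad <- sum(pi * rho^2) * (zg[2L] - zg[1L])
  expect_equal(mol$crown_volume_mm3, v_quad, tolerance = 5e-3)
})

test_that("crown region equals the CEJ-capped crown", {
  cyl <- get_cylinder()
  expect_equal(signed_volume(crown_region(cyl)), pi * 25 * 8,
               tolerance = 1e-3)
  flat <- make_molar_like(tooth_spec(cej_wave_amp_mm = 0),
                          resolution = mesh_resolution(preset = "fast"))
  expect_equal(max(abs(flat$cej_curve[, 3])), 0, tolerance = 1e-9)
  # planar CEJ: the crown cut is the z = 0 plane
  expect_equal(min(crown_region(flat)$vertices[, 3]), 0, tolerance = 1e-6)
  mol <- get_molar_fast()
  expect_equal(voxel_volume(crown_region(mol), 0.1),
               mol$crown_volume_mm3, tolerance = 0.01)
})

test_that("tooth spec validates and round-trips through YAML", {
  expect_error(tooth_spec(crown_height_mm = 0), "crown_height")
  expect_error(tooth_spec(cej_wave_amp_mm = -1), "cej_wave_amp")
  expect_error(tooth_spec(cross_section_exponent = 1.5), "exponent")
  spec <- tooth_spec(cusp_height_mm = 1.2, seed = 11L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tooth_spec(spec, path)
  expect_equal(read_tooth_spec(path), spec)
})

test_that("fixture export writes STL plus a CEJ sidecar that reloads", {
  cyl <- get_cylinder()
  stl <- withr::local_tempfile(fileext = ".stl")
  sidecar <- withr::local_tempfile(fileext = ".txt")
  write_stl(cyl$mesh, stl)
  write_cej_curve(cyl$cej_curve, sidecar)
  back <- read_cej_curve(sidecar)
  expect_equal(back, unname(cyl$cej_curve), tolerance = 1e-6)
  m <- read_stl(stl)
  expect_equal(signed_volume(m), signed_volume(cyl$mesh), tolerance = 1e-4)
})
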