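test_that("a tooth loaded from STL reproduces the analytic pipeline", {
  cyl <- get_cylinder()
  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(cyl$mesh, stl)
  mesh <- read_stl(stl)
  tooth <- tooth_from_mesh(mesh, cyl$cej_curve,
                           resolution = mesh_resolution(preset = "fast"))
  expect_true(validate_watertight(tooth$mesh)$pass)
  expect_equal(tooth$crown_volume_mm3, pi * 25 * 8,
               tolerance = 0.005 * pi * 200)
  # full preparation through the ray-cast fields matches the closed form
  r <- run_removal(tooth, 8, 0, 1, 1)
  expect_equal(r$removed_pct, cylinder_frustum_pct(5, 8, 8, 1, 1),
               tolerance = 1, ignore_attr = TRUE)
})

test_that("unit scaling slots into the mesh-input workflow", {
  cyl <- make_cylinder_tooth(2.5, 4, root_length_mm = 4)
  # a half-scale scan with reference marks 5 mm apart that are known to be
  # 10 mm apart on the physical model
  scaled <- scale_to_reference(
    cyl$mesh, scale_reference(c(-2.5, 0, 0), c(2.5, 0, 0), 10))
  expect_equal(signed_volume(scaled), 8 * signed_volume(cyl$mesh),
               tolerance = 1e-6)
})
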