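test_that("removal percentage arithmetic and consistency guards", {
  cube <- cube_mesh(2)
  expect_equal(removal_percent(cube, cube)$removed_pct, 0)
  # half-height slab: exactly 50 vol%
  half <- cube
  half$vertices[half$vertices[, 3] > 1, 3] <- 1
  expect_equal(removal_percent(cube, half)$removed_pct, 50,
               tolerance = 1e-9)
  big <- scale_to_reference(cube, scale_reference(c(0, 0, 0), c(1, 0, 0), 1.1))
  expect_error(removal_percent(cube, big), "Boolean leak")
})

test_that("cylinder full-crown removal matches the frustum percentage", {
  cyl <- get_cylinder()
  r <- run_removal(cyl, 10, 0, 1, 0.5)
  expect_equal(r$removed_pct, cylinder_frustum_pct(5, 8, 10, 1, 0.5),
               tolerance = 0.5, ignore_attr = TRUE)
})

test_that("voxel oracle percentage agrees on analytic cases", {
  cube <- cube_mesh(2)
  expect_equal(voxel_oracle_percent(cube, cube, 0.1), 0)
  half <- cube
  half$vertices[half$vertices[, 3] > 1, 3] <- 1
  expect_equal(voxel_oracle_percent(cube, half, 0.05), 50, tolerance = 1)
})

test_that("root removal by the CEJ fan cap is exact on the cylinder", {
  cyl <- get_cylinder()
  crown <- cut_root(cyl$mesh, cyl$cej_curve,
                    resolution = mesh_resolution(preset = "fast"))
  expect_true(validate_watertight(crown)$pass)
  expect_equal(signed_volume(crown), pi * 25 * 8, tolerance = 0.01 * pi * 200)
})

test_that("wavy-CEJ root removal matches the voxel oracle", {
  mol <- get_molar_fast()
  crown <- cut_root(mol$mesh, mol$cej_curve,
                    resolution = mesh_resolution(preset = "fast"))
  expect_true(validate_watertight(crown)$pass)
  vox <- voxel_volume(crown, 0.1)
  expect_equal(signed_volume(crown), vox, tolerance = 0.01 * vox)
  # and the re-meshed crown agrees with the model's cached crown
  expect_equal(signed_volume(crown), mol$crown_volume_mm3,
               tolerance = 0.01 * mol$crown_volume_mm3)
})

test_that("malformed CEJ curves are rejected", {
  mol <- get_molar_fast()
  n_cej <- nrow(mol$cej_curve)
  open_curve <- mol$cej_curve[seq_len(floor(0.6 * n_cej)), ]  # big closing gap
  expect_error(cut_root(mol$mesh, open_curve), "close")
  theta <- seq(0, 2 * pi, length.out = 65L)[-65L]
  wobble <- cbind(cos(3 * theta), sin(2 * theta), 0)  # theta not monotone
  expect_error(cut_root(mol$mesh, wobble), "star-shaped")
})

test_that("the root never enters the vol%: denominator invariance", {
  short <- make_cylinder_tooth(5, 8, root_length_mm = 4)
  long <- make_cylinder_tooth(5, 8, root_length_mm = 12)
  expect_equal(short$crown_volume_mm3, long$crown_volume_mm3,
               tolerance = 1e-9)
  r_short <- run_removal(short, 8, 0.6, 2, 1)
  r_long <- run_removal(long, 8, 0.6, 2, 1)
  expect_equal(r_short$removed_pct, r_long$removed_pct, tolerance = 1e-6)
})
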