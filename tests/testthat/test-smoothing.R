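test_that("seam smoothing is the identity when disabled or unneeded", {
  cube <- cube_mesh(2)
  out0 <- smooth_seams(cube, iterations = 0)
  expect_identical(out0$vertices, cube$vertices)
  # a smooth sphere has no dihedral angle above the crease threshold
  sph <- icosphere(2, subdiv = 3)
  outs <- smooth_seams(sph, iterations = 10)
  expect_identical(outs$vertices, sph$vertices)
  expect_equal(attr(outs, "smoothing")$n_smoothed, 0L)
})

test_that("crease edges are smoothed and the volume change is recorded", {
  cube <- cube_mesh(2)
  out <- smooth_seams(cube, seam_band_mm = 0.8, iterations = 10)
  info <- attr(out, "smoothing")
  expect_gt(info$n_smoothed, 0L)
  expect_lt(signed_volume(out), signed_volume(cube))  # corners rounded
  expect_equal(info$delta_mm3, signed_volume(out) - signed_volume(cube),
               tolerance = 1e-9)
  expect_true(validate_watertight(out)$pass)
})

test_that("the volume guard reduces iterations instead of over-rounding", {
  cube <- cube_mesh(2)
  w <- testthat::capture_warnings(
    out <- smooth_seams(cube, seam_band_mm = 0.8, iterations = 10,
                        max_delta_mm3 = 0.02))
  expect_true(any(grepl("guard", w)))
  info <- attr(out, "smoothing")
  expect_lt(info$iterations_used, 10L)
  expect_lte(abs(info$delta_mm3), 0.02 + 1e-12)
})

test_that("prepared-tooth smoothing stays within the removed-volume guard", {
  cyl <- get_cylinder()
  prep <- suppressWarnings(apply_preparation(cyl, prep_params(8, 0.8, 2, 1),
                                             crown_only = TRUE))
  res <- removal_percent(cyl, prep)
  expect_lte(abs(prep$provenance$smoothing_delta_mm3),
             0.005 * res$removed_mm3 + 1e-9)
})
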