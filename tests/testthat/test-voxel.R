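test_that("voxel volume converges to the closed form on analytic solids", {
  expect_equal(voxel_volume(cube_mesh(1), 0.05), 1.0, tolerance = 0.01)
  sph <- icosphere(2, subdiv = 4)
  expect_equal(voxel_volume(sph, 0.05), signed_volume(sph),
               tolerance = 0.01)
})

test_that("voxel oracle guards its parameters and resources", {
  expect_error(voxel_volume(cube_mesh(1), 0), "positive")
  expect_error(voxel_volume(cube_mesh(1), -0.1), "positive")
  expect_error(voxel_volume(cube_mesh(100), 0.01, max_voxels = 1e6),
               "exceeds")
})

test_that("point classification uses a majority vote over three axes", {
  cube <- cube_mesh(2)
  pts <- rbind(c(1, 1, 1), c(0.1, 0.1, 0.1), c(2.5, 1, 1),
               c(-0.2, 1, 1), c(1.99, 1.99, 1.99))
  expect_equal(point_in_mesh(cube, pts),
               c(TRUE, TRUE, FALSE, FALSE, TRUE))
  sph <- icosphere(1, subdiv = 3)
  set.seed(7)
  p <- matrix(runif(300, -1.2, 1.2), ncol = 3)
  inside <- point_in_mesh(sph, p)
  rad <- sqrt(rowSums(p^2))
  # away from the surface the classification matches the radius test
  clear <- abs(rad - 1) > 0.05
  expect_equal(inside[clear], (rad < 1)[clear])
})
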