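test_that("STL reading merges the facet soup into shared vertices", {
  cube <- cube_mesh(1)
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(ascii_stl_text(cube, "cube"), path)
  m <- read_stl(path)
  expect_equal(nrow(m$vertices), 8L)   # 36 raw corners -> 8 unique
  expect_equal(nrow(m$faces), 12L)
  expect_equal(signed_volume(m), 1.0, tolerance = 1e-9)
})

test_that("binary STL round-trips to the same mesh as ASCII", {
  cube <- cube_mesh(1)
  # binary STL written independently of the package writer
  path <- withr::local_tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(raw(80L), con)
  writeBin(nrow(cube$faces), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(cube$faces))) {
    tri <- cube$vertices[cube$faces[i, ], , drop = FALSE]
    writeBin(as.numeric(c(0, 0, 0, t(tri))), con, size = 4L,
             endian = "little")
    writeBin(as.integer(0), con, size = 2L, endian = "little")
  }
  close(con)
  m <- read_stl(path)
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)
  expect_equal(signed_volume(m), 1.0, tolerance = 1e-6)
})

test_that("read_stl rejects unreadable input and flags open meshes", {
  expect_error(read_stl(tempfile()), "not found")
  path <- withr::local_tempfile(fileext = ".stl")
  file.create(path)
  expect_error(read_stl(path), "empty")
  open_cube <- cube_mesh(1)
  open_cube$faces <- open_cube$faces[-1L, , drop = FALSE]
  path2 <- withr::local_tempfile(fileext = ".stl")
  writeLines(ascii_stl_text(open_cube), path2)
  expect_warning(read_stl(path2), "boundary")
})

test_that("OBJ output round-trips vertices, faces and volume", {
  cube <- cube_mesh(1)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(cube, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), 8L)
  expect_equal(sum(startsWith(lines, "f ")), 12L)
  back <- read_obj(path)
  expect_equal(back$vertices, cube$vertices, tolerance = 1e-9)
  expect_equal(signed_volume(back), signed_volume(cube), tolerance = 1e-12)
  sph <- icosphere(2, subdiv = 3)
  path2 <- withr::local_tempfile(fileext = ".obj")
  write_obj(sph, path2)
  back2 <- read_obj(path2)
  expect_equal(nrow(back2$faces), nrow(sph$faces))
  expect_equal(signed_volume(back2), signed_volume(sph), tolerance = 1e-9)
})

test_that("STL writer round-trips face count and volume", {
  sph <- icosphere(1.5, subdiv = 3)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(sph, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(sph$faces))
  expect_equal(signed_volume(back), signed_volume(sph),
               tolerance = 1e-6)
})

test_that("reference scaling is uniform about the centroid", {
  cube <- cube_mesh(1)
  same <- scale_to_reference(cube, scale_reference(c(0, 0, 0), c(10, 0, 0), 10))
  expect_equal(same$vertices, cube$vertices, tolerance = 1e-12)
  doubled <- scale_to_reference(cube, scale_reference(c(0, 0, 0), c(10, 0, 0), 20))
  expect_equal(signed_volume(doubled), 8, tolerance = 1e-9)
  # markers on opposite cube corners, true distance 2*sqrt(3) -> edge 2
  diag <- scale_to_reference(cube, scale_reference(c(0, 0, 0), c(1, 1, 1),
                                                   2 * sqrt(3)))
  expect_equal(signed_volume(diag), 8, tolerance = 1e-9)
  expect_error(scale_to_reference(cube, scale_reference(c(0, 0, 0),
                                                        c(0, 0, 0), 1)),
               "markers must|degenerate")
})

test_that("scaling obeys the cube law for arbitrary factors", {
  sph <- icosphere(1, subdiv = 2)
  v0 <- signed_volume(sph)
  for (s in c(0.3, 1.7, 2.5, 4)) {
    scaled <- scale_to_reference(sph, scale_reference(c(-1, 0, 0), c(1, 0, 0),
                                                      2 * s))
    expect_equal(signed_volume(scaled), s^3 * v0, tolerance = 1e-9)
  }
})

test_that("signed volume matches closed forms and flags bad input", {
  expect_equal(signed_volume(cube_mesh(1)), 1.0, tolerance = 1e-12)
  sph <- icosphere(2, subdiv = 4)
  expect_equal(signed_volume(sph), 4 / 3 * pi * 8, tolerance = 5e-3)
  flipped <- reverse_orientation(cube_mesh(1))
  expect_equal(signed_volume(flipped), -1.0, tolerance = 1e-12)
  open_cube <- cube_mesh(1)
  open_cube$faces <- open_cube$faces[-1L, , drop = FALSE]
  expect_error(signed_volume(open_cube), "boundary")
})

test_that("watertightness report diagnoses boundary edges and overlaps", {
  expect_true(validate_watertight(cube_mesh(1))$pass)
  open_cube <- cube_mesh(1)
  open_cube$faces <- open_cube$faces[-1L, , drop = FALSE]
  rep <- validate_watertight(open_cube)
  expect_false(rep$pass)
  expect_equal(rep$boundary_edges, 3L)
  # two interpenetrating cubes in one mesh self-intersect
  a <- cube_mesh(1)
  b <- translate_mesh(cube_mesh(1), c(0.47, 0.53, 0.61))
  both <- tri_mesh(rbind(a$vertices, b$vertices),
                   rbind(a$faces, b$faces + nrow(a$vertices)), "overlap")
  rep2 <- validate_watertight(both, check_self_intersections = TRUE)
  expect_gt(rep2$self_intersections, 0L)
})
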