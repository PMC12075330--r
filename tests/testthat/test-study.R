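# Synthetic results table over the full factorial grid with a known linear
# response; lets the summary operations be checked exactly without geometry.
fake_results <- function(grid = study_grid(),
                         fn = function(a, c, d, o) {
                           60 - 6 * d + 8 * c + 0.5 * a + 3 * o
                         }) {
  cells <- grid_cells(grid)
  pct <- fn(cells$angle_deg, cells$chamfer_mm, cells$finish_line_mm,
            cells$occlusal_mm)
  out <- cbind(cells, removed_mm3 = pct * 5, removed_pct = pct,
               smoothing_delta_pct = 0, status = "ok",
               stringsAsFactors = FALSE)
  attr(out, "grid") <- grid
  class(out) <- c("results_table", "data.frame")
  out
}

test_that("the default grid enumerates the full factorial design", {
  grid <- study_grid()
  expect_equal(n_designs(grid), 720L)
  cells <- grid_cells(grid)
  expect_equal(nrow(cells), 720L)
  expect_equal(nrow(unique(cells)), 720L)
  expect_error(study_grid(angle_deg = c(8, 6)), "increasing")
  expect_error(study_grid(chamfer_mm = numeric(0)), "non-empty")
})

test_that("a factorial run returns one row per cell with removal values", {
  cyl <- get_cylinder()
  grid <- study_grid(angle_deg = c(6, 12), chamfer_mm = c(0.4, 1.2),
                     finish_line_mm = 2, occlusal_mm = 1)
  res <- run_factorial_study(cyl, grid)
  expect_s3_class(res, "results_table")
  expect_equal(nrow(res), 4L)
  expect_true(all(res$status == "ok"))
  # strictly increasing along the chamfer axis at each angle
  for (a in c(6, 12)) {
    sl <- res[res$angle_deg == a, ]
    expect_true(all(diff(sl$removed_pct[order(sl$chamfer_mm)]) > 0))
  }
  # and the zero-chamfer closed form brackets the values sensibly
  expect_gt(min(res$removed_pct), cylinder_frustum_pct(5, 8, 6, 2, 1) - 0.5)
  single <- run_factorial_study(cyl, study_grid(8, 0.4, 2, 1))
  expect_equal(nrow(single), 1L)
})

test_that("increment tables report per-step ranges with the right labels", {
  flat <- fake_results(fn = function(a, c, d, o) 42)
  tab <- increment_table(flat, "finish_line")
  expect_equal(tab$min_vol_pct, rep(0, 5))
  expect_equal(tab$max_vol_pct, rep(0, 5))
  lin <- fake_results()
  tab2 <- increment_table(lin, "finish_line")
  expect_equal(tab2$step,
               c("6 to 5 mm", "5 to 4 mm", "4 to 3 mm", "3 to 2 mm",
                 "2 to 1 mm"))
  expect_equal(tab2$min_vol_pct, rep(6, 5))   # -6 per mm toward the CEJ
  expect_equal(tab2$max_vol_pct, rep(6, 5))
  tab3 <- increment_table(lin, "chamfer")
  expect_equal(tab3$step[1L], "0.2 to 0.4 mm")
  expect_equal(tab3$mean_vol_pct, rep(8 * 0.2, 7), tolerance = 1e-9)
  tab4 <- increment_table(lin, "angle")
  expect_equal(tab4$mean_vol_pct, rep(1, 4), tolerance = 1e-9)
})

test_that("increment table on the cylinder matches closed-form differences", {
  cyl <- get_cylinder()
  grid <- study_grid(angle_deg = c(6, 10, 14), chamfer_mm = 0.001,
                     finish_line_mm = 2, occlusal_mm = 1)
  res <- run_factorial_study(cyl, grid)
  tab <- increment_table(res, "angle")
  closed <- vapply(c(6, 10, 14), function(a) {
    cylinder_frustum_pct(5, 8, a, 2, 1)
  }, numeric(1L))
  expect_equal(tab$mean_vol_pct, diff(closed), tolerance = 0.5)
})

test_that("effect ranking orders parameters by mean swing", {
  lin <- fake_results()
  rk <- effect_ranking(lin)
  # swings: finish 30, chamfer 11.2, angle 4, occlusal 3
  expect_equal(rk$parameter,
               c("finish_line", "chamfer", "angle", "occlusal"))
  expect_equal(rk$mean_swing_vol_pct, c(30, 11.2, 4, 3), tolerance = 1e-9)
  expect_false(attr(rk, "ties"))
  flat <- fake_results(fn = function(a, c, d, o) 42)
  expect_message(rk2 <- effect_ranking(flat), "tied")
  expect_true(attr(rk2, "ties"))
  expect_equal(rk2$parameter[1L], "finish_line")  # declared order
})

test_that("material comparison maps spaces onto preparation parameters", {
  cyl <- get_cylinder()
  mats <- list(
    material_spec("A (adhesive)", 1.0, 1.0, group = "lithium disilicate"),
    material_spec("Z (zirconia)", 0.5, 0.5, group = "monolithic zirconia",
                  flag_partial_coverage = TRUE))
  tab <- material_comparison(cyl, mats, angle_deg = 8)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$finish_line_mm, rep(c(6, 4, 1), 2))
  expect_true(all(tab$status == "ok"))
  expect_equal(tab$flagged,
               c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  # onlay < partial < full crown for every material
  for (m in unique(tab$material)) {
    v <- tab$removed_pct[tab$material == m]
    expect_true(all(diff(v) > 0))
  }
  expect_error(material_spec("bad", 0, 1), "positive")
})

test_that("the built-in catalog carries the published space requirements", {
  mats <- default_materials()
  df <- data.frame(name = vapply(mats, `[[`, "", "name"),
                   occ = vapply(mats, `[[`, 0, "occlusal_space_mm"),
                   circ = vapply(mats, `[[`, 0, "circumferential_space_mm"))
  adhesive <- df[grepl("adhesive cementation", df$name), ][1L, ]
  expect_equal(unname(adhesive$occ), 1.0)
  expect_equal(unname(adhesive$circ), 1.0)
  lava <- df[grepl("Lava", df$name), ]
  expect_equal(unname(lava$occ), 0.5)
  expect_equal(unname(lava$circ), 0.5)
})

test_that("CSV export round-trips at the printed precision", {
  lin <- fake_results()
  path <- withr::local_tempfile(fileext = ".csv")
  export_results(lin, path)
  expect_equal(length(readLines(path)), 721L)  # header + one row per design
  back <- read_results(path)
  expect_equal(back$removed_pct, round(lin$removed_pct, 1))
  expect_equal(back$removed_mm3, round(lin$removed_mm3, 3))
  empty <- lin[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_results(empty, path2)
  expect_equal(length(readLines(path2)), 1L)
})
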