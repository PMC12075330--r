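# Factorial study layer: sweep the four preparation parameters over a grid,
# summarise per-step removal increments (min-max over the combinations of
# the other parameters), rank parameter effects, and compare restorative
# materials at their minimum layer thicknesses.

#' Factorial parameter grid
#'
#' Defaults are the full study grid: preparation angles 6-14 degrees in 2
#' degree steps, chamfer depths 0.2-1.6 mm in 0.2 mm steps, finish-line
#' distances 1-6 mm in 1 mm steps, occlusal reductions 0.5/1.0/1.5 mm -
#' 720 unique designs.
#'
#' @param angle_deg increasing vector of preparation angles (degrees).
#' @param chamfer_mm increasing vector of chamfer depths (mm).
#' @param finish_line_mm increasing vector of finish-line distances (mm).
#' @param occlusal_mm increasing vector of occlusal reductions (mm).
#' @return object of class `study_grid`.
#' @export
study_grid <- function(angle_deg = c(6, 8, 10, 12, 14),
                       chamfer_mm = seq(0.2, 1.6, by = 0.2),
                       finish_line_mm = 1:6,
                       occlusal_mm = c(0.5, 1.0, 1.5)) {
  levels <- list(angle_deg = angle_deg, chamfer_mm = chamfer_mm,
                 finish_line_mm = finish_line_mm, occlusal_mm = occlusal_mm)
  for (nm in names(levels)) {
    v <- levels[[nm]]
    if (length(v) == 0L || anyNA(v) || is.unsorted(v, strictly = TRUE)) {
      stop(nm, " levels must be non-empty and strictly increasing")
    }
  }
  structure(levels, class = "study_grid")
}

#' @export
print.study_grid <- function(x, ...) {
  cat(sprintf(
    "<study_grid: %d angles x %d chamfers x %d finish lines x %d occlusal = %d designs>\n",
    length(x$angle_deg), length(x$chamfer_mm), length(x$finish_line_mm),
    length(x$occlusal_mm), n_designs(x)))
  invisible(x)
}

#' Number of unique designs in a grid
#' @param grid a [study_grid()].
#' @return integer cell count.
#' @export
n_designs <- function(grid) {
  length(grid$angle_deg) * length(grid$chamfer_mm) *
    length(grid$finish_line_mm) * length(grid$occlusal_mm)
}

#' Enumerate the grid cells
#' @param grid a [study_grid()].
#' @return data.frame with one row per design.
#' @export
grid_cells <- function(grid) {
  expand.grid(angle_deg = grid$angle_deg, chamfer_mm = grid$chamfer_mm,
              finish_line_mm = grid$finish_line_mm,
              occlusal_mm = grid$occlusal_mm,
              KEEP.OUT.ATTRS = FALSE)
}

#' Run the factorial preparation study
#'
#' Applies every grid design to the tooth and records removed volume and
#' vol% relative to the intact crown. Per-cell geometry failures are
#' recorded (`status != "ok"`) rather than aborting; more than 5% failed
#' cells aborts with a failure manifest.
#'
#' @param tooth a `tooth_model`.
#' @param grid a [study_grid()].
#' @param resolution a [mesh_resolution()] for the per-cell re-meshing;
#'   defaults to the `"fast"` preset (factorial sweeps are volume
#'   integrations, not surface exports).
#' @param smoothing a [smoothing_settings()].
#' @param progress print a progress line every 50 cells.
#' @return a `results_table`: data.frame with columns angle_deg, chamfer_mm,
#'   finish_line_mm, occlusal_mm, removed_mm3, removed_pct,
#'   smoothing_delta_pct, status; attributes `fixture_id`, `crown_mm3`,
#'   `grid`.
#' @export
run_factorial_study <- function(tooth, grid = study_grid(),
                                resolution = mesh_resolution(preset = "fast"),
                                smoothing = smoothing_settings(),
                                progress = FALSE) {
  stopifnot(inherits(tooth, "tooth_model"), inherits(grid, "study_grid"))
  cells <- grid_cells(grid)
  n <- nrow(cells)
  removed_mm3 <- removed_pct <- sm_pct <- rep(NA_real_, n)
  status <- rep("ok", n)
  for (i in seq_len(n)) {
    p <- prep_params(cells$angle_deg[i], cells$chamfer_mm[i],
                     cells$finish_line_mm[i], cells$occlusal_mm[i])
    res <- tryCatch({
      prep <- suppressWarnings(
        apply_preparation(tooth, p, resolution = resolution,
                          smoothing = smoothing, crown_only = TRUE))
      removal_percent(tooth, prep)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
    } else {
      removed_mm3[i] <- res$removed_mm3
      removed_pct[i] <- res$removed_pct
      sm_pct[i] <- res$smoothing_delta_pct
    }
    if (progress && i %% 50L == 0L) {
      message(sprintf("  %d / %d designs", i, n))
    }
  }
  failed <- sum(status != "ok")
  if (failed > 0.05 * n) {
    stop(sprintf("factorial study failed on %d of %d cells; first: %s",
                 failed, n, status[status != "ok"][1L]))
  }
  out <- cbind(cells, removed_mm3 = removed_mm3, removed_pct = removed_pct,
               smoothing_delta_pct = sm_pct, status = status,
               stringsAsFactors = FALSE)
  attr(out, "fixture_id") <- tooth$fixture_id
  attr(out, "crown_mm3") <- tooth$crown_volume_mm3
  attr(out, "grid") <- grid
  class(out) <- c("results_table", "data.frame")
  out
}

param_columns <- c(angle = "angle_deg", chamfer = "chamfer_mm",
                   finish_line = "finish_line_mm", occlusal = "occlusal_mm")

#' Per-step increment summary for one parameter
#'
#' For each consecutive level pair of `parameter`, the change in removed
#' vol% is computed for every combination of the other three parameters;
#' the min-max range over combinations is reported. The finish-line
#' parameter is summarised in the decreasing direction (moving the margin
#' toward the CEJ increases removal), matching how its per-millimetre
#' effect is tabulated; the other parameters are summarised increasing.
#'
#' @param results a `results_table`.
#' @param parameter one of `"finish_line"`, `"chamfer"`, `"angle"`,
#'   `"occlusal"`.
#' @return data.frame of class `increment_summary`: step label, per-step
#'   `min_vol_pct`, `max_vol_pct`, `mean_vol_pct`.
#' @export
increment_table <- function(results,
                            parameter = c("finish_line", "chamfer",
                                          "angle", "occlusal")) {
  parameter <- match.arg(parameter)
  col <- param_columns[[parameter]]
  df <- results[results$status == "ok", , drop = FALSE]
  levels <- sort(unique(df[[col]]))
  if (length(levels) < 2L) stop("need at least two levels of ", parameter)
  others <- setdiff(unname(param_columns), col)
  wide <- stats::reshape(
    df[, c(others, col, "removed_pct")],
    idvar = others, timevar = col, direction = "wide")
  val_cols <- paste0("removed_pct.", levels)
  if (anyNA(wide[, val_cols])) {
    stop("missing cells for increment table of ", parameter)
  }
  decreasing <- parameter == "finish_line"
  steps <- if (decreasing) rev(seq_len(length(levels) - 1L)) else
    seq_len(length(levels) - 1L)
  unit <- if (parameter == "angle") "°" else " mm"
  rows <- lapply(steps, function(k) {
    delta <- if (decreasing) {
      wide[[val_cols[k]]] - wide[[val_cols[k + 1L]]]
    } else {
      wide[[val_cols[k + 1L]]] - wide[[val_cols[k]]]
    }
    lab <- if (decreasing) {
      sprintf("%g to %g%s", levels[k + 1L], levels[k], unit)
    } else {
      sprintf("%g to %g%s", levels[k], levels[k + 1L], unit)
    }
    data.frame(step = lab, min_vol_pct = min(delta),
               max_vol_pct = max(delta), mean_vol_pct = mean(delta),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  class(out) <- c("increment_summary", "data.frame")
  out
}

#' Rank parameter effects
#'
#' Effect size per parameter = mean absolute swing of removed vol% across
#' its full level range, averaged over the combinations of the other three
#' parameters. Ties (within `tie_tol`) are flagged and broken by the
#' declared parameter order (finish_line, chamfer, angle, occlusal).
#'
#' @param results a `results_table`.
#' @param tie_tol absolute tie tolerance in vol points.
#' @return data.frame ranked by decreasing effect with columns `parameter`,
#'   `mean_swing_vol_pct`, `rank`; attribute `ties` flags tied pairs.
#' @export
effect_ranking <- function(results, tie_tol = 1e-6) {
  df <- results[results$status == "ok", , drop = FALSE]
  swings <- vapply(names(param_columns), function(p) {
    col <- param_columns[[p]]
    others <- setdiff(unname(param_columns), col)
    grp <- interaction(df[others], drop = TRUE)
    mean(tapply(df$removed_pct, grp, function(x) diff(range(x))))
  }, numeric(1L))
  declared <- c("finish_line", "chamfer", "angle", "occlusal")
  ord <- order(-swings[declared], seq_along(declared))
  out <- data.frame(parameter = declared[ord],
                    mean_swing_vol_pct = unname(swings[declared][ord]),
                    rank = seq_along(declared),
                    stringsAsFactors = FALSE)
  ties <- any(abs(diff(out$mean_swing_vol_pct)) < tie_tol)
  attr(out, "ties") <- ties
  if (ties) message("effect_ranking: tied parameter swings; declared order used")
  out
}

#' Restorative material specification
#'
#' Minimum layer thicknesses from manufacturer guidance, mapped onto
#' preparation parameters: occlusal space -> occlusal reduction,
#' circumferential space at the crown margin -> chamfer depth.
#'
#' @param name material / cementation label.
#' @param occlusal_space_mm required occlusal space (mm).
#' @param circumferential_space_mm required circumferential space (mm).
#' @param group material class label (e.g. "lithium disilicate").
#' @param flag_partial_coverage if `TRUE`, onlay and partial-crown rows for
#'   this material are flagged in the comparison output.
#' @return object of class `material_spec`.
#' @export
material_spec <- function(name, occlusal_space_mm, circumferential_space_mm,
                          group = NA_character_,
                          flag_partial_coverage = FALSE) {
  if (occlusal_space_mm <= 0 || circumferential_space_mm <= 0) {
    stop("material spaces must be positive")
  }
  structure(list(name = name, occlusal_space_mm = occlusal_space_mm,
                 circumferential_space_mm = circumferential_space_mm,
                 group = group,
                 flag_partial_coverage = flag_partial_coverage),
            class = "material_spec")
}

#' Built-in material catalog
#'
#' Lithium-disilicate and monolithic-zirconia materials with their minimum
#' occlusal / circumferential space requirements. Zirconia partial-coverage
#' rows are flagged: those restoration classes are not the material's usual
#' indication, and their values are reported as computed but marked.
#'
#' @return list of [material_spec()] objects.
#' @export
default_materials <- function() {
  list(
    material_spec("IPS e.max CAD (adhesive cementation)",
                  1.0, 1.0, group = "lithium disilicate"),
    material_spec("IPS e.max CAD (self-adhesive or conventional cementation)",
                  1.5, 1.5, group = "lithium disilicate"),
    material_spec("IPS e.max ZirCAD Prime and Prime Esthetic",
                  1.0, 1.0, group = "monolithic zirconia",
                  flag_partial_coverage = TRUE),
    material_spec("3M Lava Plus", 0.5, 0.5, group = "monolithic zirconia",
                  flag_partial_coverage = TRUE),
    material_spec("Amann Girrbach Zolid", 0.5, 0.5,
                  group = "monolithic zirconia",
                  flag_partial_coverage = TRUE),
    material_spec("Kuraray Katana Zirconia HTML", 0.5, 0.5,
                  group = "monolithic zirconia",
                  flag_partial_coverage = TRUE))
}

#' Read materials from a YAML catalog
#' @param path YAML file: a list of material entries.
#' @return list of [material_spec()] objects.
#' @export
read_materials <- function(path) {
  lapply(yaml::read_yaml(path), function(m) do.call(material_spec, m))
}

#' Material comparison table
#'
#' For each material and restoration class - occlusal onlay (finish line
#' 6 mm above the CEJ), partial crown (4 mm), full crown (1 mm) - the
#' preparation is evaluated with occlusal reduction = occlusal space,
#' chamfer depth = circumferential space, at the given preparation angle,
#' and removed vol% is reported.
#'
#' @param tooth a `tooth_model`.
#' @param materials list of [material_spec()] (default [default_materials()]).
#' @param angle_deg preparation angle (default 8, a clinically achievable
#'   16 degree convergence angle).
#' @param finish_lines named numeric vector of restoration classes.
#' @param resolution a [mesh_resolution()].
#' @return data.frame: material, group, occlusal_space_mm,
#'   circumferential_space_mm, restoration, finish_line_mm, removed_pct,
#'   flagged, status.
#' @export
material_comparison <- function(tooth, materials = default_materials(),
                                angle_deg = 8,
                                finish_lines = c(onlay = 6, partial = 4,
                                                 full_crown = 1),
                                resolution = mesh_resolution(preset = "fast")) {
  stopifnot(inherits(tooth, "tooth_model"))
  rows <- list()
  for (m in materials) {
    for (k in seq_along(finish_lines)) {
      cls <- names(finish_lines)[k]
      d <- finish_lines[[k]]
      pct <- NA_real_
      status <- "ok"
      res <- tryCatch({
        p <- prep_params(angle_deg, m$circumferential_space_mm, d,
                         m$occlusal_space_mm)
        prep <- suppressWarnings(
          apply_preparation(tooth, p, resolution = resolution,
                            crown_only = TRUE))
        removal_percent(tooth, prep)$removed_pct
      }, error = function(e) e)
      if (inherits(res, "error")) status <- conditionMessage(res) else
        pct <- res
      rows[[length(rows) + 1L]] <- data.frame(
        material = m$name, group = m$group,
        occlusal_space_mm = m$occlusal_space_mm,
        circumferential_space_mm = m$circumferential_space_mm,
        restoration = cls, finish_line_mm = d,
        removed_pct = pct,
        flagged = m$flag_partial_coverage && cls != "full_crown",
        status = status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "angle_deg") <- angle_deg
  out
}

#' Export study results as CSV
#'
#' Header: angle_deg, chamfer_mm, finish_line_mm, occlusal_mm, removed_mm3,
#' removed_pct, smoothing_delta_pct, status. Volumes are printed with 3
#' decimals, percentages with 1 decimal; re-importing recovers the values
#' exactly as printed.
#'
#' @param results a `results_table` (or compatible data.frame).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_results <- function(results, path) {
  cols <- c("angle_deg", "chamfer_mm", "finish_line_mm", "occlusal_mm",
            "removed_mm3", "removed_pct", "smoothing_delta_pct", "status")
  missing <- setdiff(cols, names(results))
  if (length(missing)) stop("results missing columns: ",
                            paste(missing, collapse = ", "))
  fmt <- function(x, digits) {
    ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  }
  lines <- c(paste(cols, collapse = ","),
             if (nrow(results) > 0L) {
               paste(results$angle_deg, results$chamfer_mm,
                     results$finish_line_mm, results$occlusal_mm,
                     fmt(results$removed_mm3, 3L),
                     fmt(results$removed_pct, 1L),
                     fmt(results$smoothing_delta_pct, 3L),
                     results$status, sep = ",")
             })
  writeLines(lines, path)
  invisible(path)
}

#' Read back an exported results CSV
#' @param path CSV written by [export_results()].
#' @return data.frame.
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(rep("numeric", 7L), "character"))
}

#' Plot removed vol% against one parameter
#'
#' Thin ggplot2 layer over a results table (requires ggplot2).
#'
#' @param results a `results_table`.
#' @param x parameter for the x axis.
#' @param color parameter mapped to colour.
#' @return a ggplot object.
#' @export
plot_removal <- function(results, x = "finish_line_mm",
                         color = "chamfer_mm") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_removal requires the ggplot2 package")
  }
  df <- results[results$status == "ok", , drop = FALSE]
  df$.x <- df[[x]]
  df$.col <- factor(df[[color]])
  ggplot2::ggplot(df, ggplot2::aes(x = .x, y = removed_pct,
                                   colour = .col)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(y = "tooth substance removal [vol%]",
                  colour = color) +
    ggplot2::theme_minimal()
}
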