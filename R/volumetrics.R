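# Root removal and volumetric substance-loss quantification. The vol%
# denominator is always the intact crown: the tooth cut by the standardized
# CEJ cap surface, so the root shape never enters the computation.

# closed-curve / star-shape validation for CEJ input
validate_cej_curve <- function(curve) {
  curve <- as.matrix(curve)
  if (ncol(curve) != 3L || nrow(curve) < 8L) {
    stop("CEJ curve must be an n x 3 matrix with n >= 8")
  }
  n <- nrow(curve)
  if (sqrt(sum((curve[1L, ] - curve[n, ])^2)) < 1e-9) {
    curve <- curve[-n, , drop = FALSE]   # explicit closure: drop duplicate
    n <- n - 1L
  }
  gaps <- sqrt(rowSums((curve[c(2:n, 1L), ] - curve)^2))
  closing <- gaps[n]
  if (closing > 1e-3 && closing > 3 * max(gaps[-n])) {
    stop(sprintf("CEJ curve does not close: endpoint gap %.4g mm", closing))
  }
  th <- atan2(curve[, 2L], curve[, 1L])
  dth <- diff(c(th, th[1L]))
  dth <- atan2(sin(dth), cos(dth))
  if (!(all(dth > 0) || all(dth < 0))) {
    stop("CEJ curve is not star-shaped about the axis (theta not monotone)")
  }
  if (sum(dth) < 0) curve <- curve[rev(seq_len(n)), , drop = FALSE]
  curve
}

#' Remove the root along the CEJ
#'
#' Cuts the tooth by the standardized CEJ cap: a fan spanned by the CEJ
#' curve and the axis, with the height blended from the curve to its mean
#' level at the center (a non-planar CEJ cannot be capped by a plane).
#' Identical curve, identical cut - the digital standardization that makes
#' crown-substance percentages reproducible.
#'
#' For `tooth_model` / `prepared_tooth` input the cached crown mesh (built
#' with exactly this cap) is returned. For a raw `tri_mesh` the fields are
#' recovered by ray casting the triangles and the crown is re-meshed on the
#' structured grid.
#'
#' @param x a `tooth_model`, `prepared_tooth`, or watertight `tri_mesh`.
#' @param cej_curve closed CEJ polyline (n x 3); required for `tri_mesh`
#'   input, ignored otherwise (the model's own curve is used).
#' @param resolution a [mesh_resolution()] for the re-meshed crown.
#' @return a watertight crown-only `tri_mesh`.
#' @export
cut_root <- function(x, cej_curve = NULL,
                     resolution = mesh_resolution()) {
  if (inherits(x, "tooth_model") || inherits(x, "prepared_tooth")) {
    return(x$crown_mesh)
  }
  stopifnot(inherits(x, "tri_mesh"))
  if (is.null(cej_curve)) stop("cej_curve is required for tri_mesh input")
  curve <- validate_cej_curve(cej_curve)
  model <- tooth_from_mesh(x, curve, resolution = resolution)
  model$crown_mesh
}

#' Volumetric substance removal relative to the intact crown
#'
#' `removed_pct = 100 (V_intact - V_prepared) / V_intact`, both volumes
#' taken on crowns cut with the identical CEJ surface.
#'
#' @param intact_crown watertight `tri_mesh` of the intact crown (or a
#'   `tooth_model`, whose crown is used).
#' @param prepared_crown watertight `tri_mesh` of the prepared crown (or a
#'   `prepared_tooth`).
#' @param params optional [prep_params()] carried into the result.
#' @param fixture_id optional fixture label.
#' @return object of class `removal_result`: `removed_mm3`, `removed_pct`
#'   (0-100), `crown_mm3`, `prepared_mm3`, `smoothing_delta_pct`, `params`,
#'   `fixture_id`.
#' @export
removal_percent <- function(intact_crown, prepared_crown, params = NULL,
                            fixture_id = NA_character_) {
  if (inherits(intact_crown, "tooth_model")) {
    fixture_id <- intact_crown$fixture_id
    intact_crown <- intact_crown$crown_mesh
  }
  sm_delta <- NA_real_
  if (inherits(prepared_crown, "prepared_tooth")) {
    if (is.null(params)) params <- prepared_crown$params
    sm_delta <- prepared_crown$provenance$smoothing_delta_mm3
    prepared_crown <- prepared_crown$crown_mesh
  } else if (!is.null(attr(prepared_crown, "smoothing"))) {
    sm_delta <- attr(prepared_crown, "smoothing")$delta_mm3
  }
  v0 <- signed_volume(intact_crown)
  v1 <- signed_volume(prepared_crown)
  if (v1 > v0 * (1 + 1e-3)) {
    stop(sprintf(
      "prepared crown (%.3f mm3) exceeds intact crown (%.3f mm3): Boolean leak",
      v1, v0))
  }
  removed <- v0 - v1
  structure(list(removed_mm3 = removed,
                 removed_pct = 100 * removed / v0,
                 crown_mm3 = v0,
                 prepared_mm3 = v1,
                 smoothing_delta_pct = if (is.na(sm_delta)) NA_real_ else
                   100 * sm_delta / v0,
                 params = params,
                 fixture_id = fixture_id),
            class = "removal_result")
}

#' @export
print.removal_result <- function(x, ...) {
  cat(sprintf("<removal_result: %.1f vol%% (%.3f of %.3f mm3)>\n",
              x$removed_pct, x$removed_mm3, x$crown_mm3))
  invisible(x)
}

#' Voxel-oracle version of the removal percentage
#'
#' Same quantity as [removal_percent()], but both volumes measured with the
#' voxel oracle ([voxel_volume()]) - the independent cross-check on the
#' mesh-Boolean result.
#'
#' @param intact_crown,prepared_crown watertight crown meshes (or
#'   `tooth_model` / `prepared_tooth`).
#' @param voxel_mm voxel edge length (default 0.05 mm).
#' @return removed volume percentage (0-100).
#' @export
voxel_oracle_percent <- function(intact_crown, prepared_crown,
                                 voxel_mm = 0.05) {
  if (inherits(intact_crown, "tooth_model")) {
    intact_crown <- intact_crown$crown_mesh
  }
  if (inherits(prepared_crown, "prepared_tooth")) {
    prepared_crown <- prepared_crown$crown_mesh
  }
  v0 <- voxel_volume(intact_crown, voxel_mm)
  v1 <- voxel_volume(prepared_crown, voxel_mm)
  100 * (v0 - v1) / v0
}
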