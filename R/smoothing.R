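# Seam smoothing after Boolean subtraction. Boolean seams (margin floor,
# wall/occlusal junction) are detected by dihedral angle; vertices within a
# band of those seams get Taubin smoothing (volume-conserving pair of
# positive/negative Laplacian steps). A volume guard keeps the smoothing
# from biasing the volumetric result: excessive rounding would underestimate
# substance removal.

#' Seam smoothing settings
#'
#' @param seam_band_mm vertices within this distance of a seam edge move.
#' @param iterations Taubin iteration count (each = one lambda + one mu step).
#' @param lambda,mu Taubin weights.
#' @param dihedral_deg crease threshold: edges whose adjacent-face normals
#'   differ by more than this are seams.
#' @return a list of class `smoothing_settings`.
#' @export
smoothing_settings <- function(seam_band_mm = 0.3, iterations = 10L,
                               lambda = 0.5, mu = -0.53,
                               dihedral_deg = 45) {
  structure(list(seam_band_mm = seam_band_mm,
                 iterations = as.integer(iterations),
                 lambda = lambda, mu = mu,
                 dihedral_deg = dihedral_deg),
            class = "smoothing_settings")
}

# unique undirected edges + the two adjacent faces (NA if boundary)
edge_face_table <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  nv <- nrow(mesh$vertices)
  i <- c(f[, 1L], f[, 2L], f[, 3L])
  j <- c(f[, 2L], f[, 3L], f[, 1L])
  fid <- rep(seq_len(nf), times = 3L)
  key <- (pmin(i, j) - 1) * as.double(nv) + pmax(i, j)
  o <- order(key)
  key <- key[o]
  # endpoints recovered from the key (lo = a, hi = b)
  a <- floor((key - 1) / nv) + 1
  b <- key - (a - 1) * nv
  fid <- fid[o]
  first <- !duplicated(key)
  idx1 <- which(first)
  nxt <- c(idx1[-1L] - 1L, length(key))
  f2 <- ifelse(nxt > idx1, fid[pmin(idx1 + 1L, length(fid))], NA_integer_)
  list(a = as.integer(a[first]), b = as.integer(b[first]),
       f1 = fid[idx1], f2 = as.integer(f2))
}

# graph-distance band around a vertex seed set (edge-length relaxation)
vertices_within_band <- function(mesh, seeds, band, rounds = 12L) {
  nv <- nrow(mesh$vertices)
  et <- edge_face_table(mesh)
  ea <- c(et$a, et$b)
  eb <- c(et$b, et$a)
  len <- sqrt(rowSums((mesh$vertices[et$a, , drop = FALSE] -
                         mesh$vertices[et$b, , drop = FALSE])^2))
  len <- c(len, len)
  d <- rep(Inf, nv)
  d[seeds] <- 0
  for (r in seq_len(rounds)) {
    cand <- d[ea] + len
    better <- cand < d[eb] - 1e-12
    if (!any(better)) break
    cb <- eb[better]
    cc <- cand[better]
    o <- order(cb, cc)
    cb <- cb[o]
    cc <- cc[o]
    firstb <- !duplicated(cb)
    d[cb[firstb]] <- pmin(d[cb[firstb]], cc[firstb])
  }
  which(d <= band)
}

#' Smooth Boolean seams of a prepared mesh
#'
#' Detects seam edges (dihedral angle above threshold), then applies Taubin
#' smoothing restricted to vertices within `seam_band_mm` of a seam. The
#' induced volume change is recorded; if it exceeds `max_delta_mm3` the
#' iteration count is halved with a warning until the guard holds
#' (deliberately avoiding rounding that would bias the volumetric result).
#'
#' @param mesh a watertight `tri_mesh`.
#' @param seam_band_mm band width around seam edges (mm).
#' @param iterations Taubin iterations; 0 returns the mesh unchanged.
#' @param settings optional [smoothing_settings()] overriding the above.
#' @param max_delta_mm3 volume-change guard (mm^3), default `Inf`.
#' @return the smoothed `tri_mesh`, with attribute `"smoothing"` =
#'   list(delta_mm3, iterations_used, n_smoothed).
#' @export
smooth_seams <- function(mesh, seam_band_mm = 0.3, iterations = 10L,
                         settings = NULL, max_delta_mm3 = Inf) {
  if (is.null(settings)) {
    settings <- smoothing_settings(seam_band_mm = seam_band_mm,
                                   iterations = iterations)
  }
  info <- list(delta_mm3 = 0, iterations_used = 0L, n_smoothed = 0L)
  if (settings$iterations <= 0L) {
    attr(mesh, "smoothing") <- info
    return(mesh)
  }
  et <- edge_face_table(mesh)
  nrm <- face_normals(mesh)
  both <- !is.na(et$f2)
  cosang <- rowSums(nrm[et$f1[both], , drop = FALSE] *
                      nrm[et$f2[both], , drop = FALSE])
  crease <- acos(pmin(pmax(cosang, -1), 1)) > settings$dihedral_deg * pi / 180
  seam_verts <- unique(c(et$a[both][crease], et$b[both][crease]))
  if (length(seam_verts) == 0L) {
    attr(mesh, "smoothing") <- info
    return(mesh)
  }
  move <- vertices_within_band(mesh, seam_verts, settings$seam_band_mm)
  # neighbour averaging structure restricted to moving vertices
  ea <- c(et$a, et$b)
  eb <- c(et$b, et$a)
  keep <- ea %in% move
  ctr <- ea[keep]
  nbr <- eb[keep]
  deg <- tabulate(ctr, nbins = nrow(mesh$vertices))[move]
  ctr_pos <- match(ctr, move)
  v0 <- mesh$vertices
  vol0 <- signed_volume(mesh, check = FALSE)
  iters <- settings$iterations
  repeat {
    v <- v0
    for (it in seq_len(iters)) {
      for (fac in c(settings$lambda, settings$mu)) {
        nb_sum <- rowsum(v[nbr, , drop = FALSE], ctr_pos, reorder = TRUE)
        mean_nb <- nb_sum / deg
        v[move, ] <- v[move, , drop = FALSE] +
          fac * (mean_nb - v[move, , drop = FALSE])
      }
    }
    out <- tri_mesh(v, mesh$faces, mesh$name)
    delta <- signed_volume(out, check = FALSE) - vol0
    if (abs(delta) <= max_delta_mm3 || iters == 0L) break
    iters <- iters %/% 2L
    warning(sprintf(
      "seam smoothing volume change %.4g mm3 exceeds guard; retrying with %d iterations",
      delta, iters))
  }
  attr(out, "smoothing") <- list(delta_mm3 = delta, iterations_used = iters,
                                 n_smoothed = length(move))
  out
}
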