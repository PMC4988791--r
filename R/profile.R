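#' Profile sampling configuration
#'
#' Intensity profiles are sampled at positions
#' \eqn{s_j = (j - \Delta/2)\,\ell} for \eqn{j = 0..\Delta} along each
#' vertex's outward normal, so \eqn{k = \Delta + 1} samples symmetric about
#' the surface.  The defaults implement step size \eqn{\ell} = half the
#' voxel size and \eqn{\Delta = 2 \times 2\,\mathrm{mm} / \ell}, i.e. a
#' profile spanning +/- 2 mm.
#'
#' @param voxel_mm acquisition voxel size (mm); used for the default step.
#' @param step_mm step size \eqn{\ell} in mm (default \code{voxel_mm / 2}).
#' @param n_steps \eqn{\Delta}, an even integer (default
#'   \code{2 * 2 / step_mm} rounded to the nearest even integer).
#' @return An object of class \code{profile_config} with elements
#'   \code{step_mm}, \code{n_steps}, \code{k}, \code{positions}.
#' @export
profile_config <- function(voxel_mm = 0.5, step_mm = voxel_mm / 2,
                           n_steps = NULL) {
  stopifnot(step_mm > 0)
  if (is.null(n_steps)) n_steps <- as.integer(round(2 * 2 / step_mm))
  n_steps <- as.integer(n_steps)
  if (n_steps %% 2L != 0L) stop("n_steps (Delta) must be even")
  positions <- (0:n_steps - n_steps / 2) * step_mm
  structure(list(step_mm = step_mm, n_steps = n_steps,
                 k = n_steps + 1L, positions = positions),
            class = "profile_config")
}

# trilinear interpolation of a 3D volume (with affine) at world points;
# returns NA outside the grid support
trilinear_sample <- function(volume, affine, points) {
  d <- dim(volume)
  inv <- solve(affine)
  ijk <- cbind(points, 1) %*% t(inv)  # continuous 0-based voxel coords
  x <- ijk[, 1]; y <- ijk[, 2]; z <- ijk[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ok <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
        x0 <= d[1] - 2 & y0 <= d[2] - 2 & z0 <= d[3] - 2
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  i <- x0[ok]; j <- y0[ok]; k <- z0[ok]
  gx <- fx[ok]; gy <- fy[ok]; gz <- fz[ok]
  at <- function(di, dj, dk)
    volume[1L + (i + di) + d[1] * ((j + dj) + d[2] * (k + dk))]
  out[ok] <-
    at(0, 0, 0) * (1 - gx) * (1 - gy) * (1 - gz) +
    at(1, 0, 0) * gx       * (1 - gy) * (1 - gz) +
    at(0, 1, 0) * (1 - gx) * gy       * (1 - gz) +
    at(1, 1, 0) * gx       * gy       * (1 - gz) +
    at(0, 0, 1) * (1 - gx) * (1 - gy) * gz +
    at(1, 0, 1) * gx       * (1 - gy) * gz +
    at(0, 1, 1) * (1 - gx) * gy       * gz +
    at(1, 1, 1) * gx       * gy       * gz
  out
}

#' Sample an intensity profile along a normal
#'
#' Trilinear interpolation of the volume at \eqn{p + s_j n} for each sample
#' position of the configuration.  Samples outside the field of view are
#' NA; if more than 25\% of the samples fall outside, the profile is
#' rejected.
#'
#' @param volume 3D numeric array.
#' @param affine 4x4 voxel-to-world affine of the volume.
#' @param point length-3 world-mm position on the surface.
#' @param normal length-3 unit outward normal.
#' @param config a \code{\link{profile_config}}.
#' @return Numeric vector of k intensities (possibly with NAs).
#' @export
sample_profile <- function(volume, affine, point, normal, config) {
  pts <- outer(config$positions, normal) +
    matrix(point, config$k, 3, byrow = TRUE)
  v <- trilinear_sample(volume, affine, pts)
  if (mean(is.na(v)) > 0.25)
    stop("profile-out-of-bounds: more than 25% of samples outside the volume")
  v
}

# profiles for all mesh vertices at once: returns n_vertices x k matrix
sample_profiles_mesh <- function(volume, affine, mesh, config) {
  nv <- nrow(mesh$vertices)
  pts <- matrix(0, nv * config$k, 3)
  for (j in seq_len(config$k)) {
    rows <- (j - 1L) * nv + seq_len(nv)
    pts[rows, ] <- mesh$vertices + config$positions[j] * mesh$normals
  }
  v <- trilinear_sample(volume, affine, pts)
  P <- matrix(v, nv, config$k)
  frac_out <- rowMeans(is.na(P))
  if (any(frac_out > 0.25))
    stop(sprintf("profile-out-of-bounds at %d vertex/vertices (first: %d)",
                 sum(frac_out > 0.25), which(frac_out > 0.25)[1]))
  P
}

#' Modal intensity inside a mask
#'
#' Mode of the intensity histogram inside the mask: 100 equal-width bins
#' between the 1st and 99th intensity percentiles, the mode being the
#' center of the fullest bin.  Deterministic and robust to outliers; used
#' as the structure's representative ("Self") intensity.
#'
#' @param volume 3D numeric array.
#' @param mask a \code{\link{voxel_mask}} on the same grid.
#' @param n_bins number of histogram bins (default 100).
#' @return Scalar modal intensity.
#' @export
modal_intensity <- function(volume, mask, n_bins = 100L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!identical(dim(volume), dim(mask$data)))
    stop("volume and mask grids differ")
  vals <- volume[mask$data]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("modal intensity of an empty mask is undefined")
  qs <- stats::quantile(vals, c(0.01, 0.99), names = FALSE, type = 7)
  if (qs[2] <= qs[1]) return(qs[1])  # (near-)constant region
  br <- seq(qs[1], qs[2], length.out = n_bins + 1L)
  inb <- vals[vals >= qs[1] & vals <= qs[2]]
  counts <- tabulate(pmin(pmax(findInterval(inb, br, rightmost.closed = TRUE),
                               1L), n_bins), nbins = n_bins)
  i <- which.max(counts)
  (br[i] + br[i + 1L]) / 2
}
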