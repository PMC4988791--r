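#' Normalized modal intensity inside a structure
#'
#' For relative (T2*-like) modalities the structure's modal intensity is
#' divided by the mean white-matter intensity to remove arbitrary global
#' scaling; quantitative (QSM-like) modalities are used as-is.  The
#' structure mask is expected to be the (eroded) rater-intersection mask;
#' erosion policy is the caller's.
#'
#' @param volume 3D numeric array.
#' @param structure_mask \code{voxel_mask} of the structure.
#' @param wm_mask \code{voxel_mask} of white matter (ignored in absolute
#'   mode).
#' @param mode \code{"relative"} or \code{"absolute"}.
#' @return Scalar normalized intensity.
#' @export
normalized_modal_intensity <- function(volume, structure_mask, wm_mask = NULL,
                                       mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  m <- modal_intensity(volume, structure_mask)
  if (mode == "absolute") return(m)
  if (is.null(wm_mask) || !any(wm_mask$data))
    stop("relative normalization requires a non-empty white-matter mask")
  wm <- mean(volume[wm_mask$data])
  if (!is.finite(wm) || wm == 0) stop("white-matter mean is zero or non-finite")
  m / wm
}

#' Intersection-then-erode rater mask
#'
#' Conservative combination of two raters' masks for intensity analysis:
#' voxelwise intersection followed by one pass of 3x3x3 box erosion.
#'
#' @param a,b \code{voxel_mask} objects on the same grid.
#' @return Eroded intersection \code{voxel_mask}.
#' @export
intersection_eroded_mask <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("masks are on different grids")
  erode_mask(voxel_mask(a$data & b$data, a$affine))
}

#' Per-group volume-vs-intensity regression
#'
#' Ordinary least squares of segmentation volume on normalized modal
#' intensity, fitted within each group and pooled, with two-sided slope
#' p-values and a significance flag at 0.05.
#'
#' @param records data.frame with columns \code{volume} (mm^3),
#'   \code{intensity} and \code{group}.
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame with one row per group plus a pooled row: columns
#'   \code{group}, \code{n}, \code{slope}, \code{intercept}, \code{p},
#'   \code{significant}.
#' @export
group_intensity_regression <- function(records, alpha = 0.05) {
  stopifnot(all(c("volume", "intensity", "group") %in% names(records)))
  fit_one <- function(df, label) {
    if (nrow(df) < 3L)
      stop(sprintf("group '%s' has fewer than 3 subjects", label))
    if (stats::sd(df$intensity) == 0)
      stop(sprintf("degenerate (constant) intensity predictor in group '%s'",
                   label))
    fm <- stats::lm(volume ~ intensity, data = df)
    co <- summary(fm)$coefficients
    data.frame(group = label, n = nrow(df),
               slope = co["intensity", "Estimate"],
               intercept = co["(Intercept)", "Estimate"],
               p = co["intensity", "Pr(>|t|)"],
               significant = co["intensity", "Pr(>|t|)"] <= alpha,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(records, records$group), function(df)
    fit_one(df, as.character(df$group[1]))))
  out <- rbind(out, fit_one(records, "pooled"))
  rownames(out) <- NULL
  out
}
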