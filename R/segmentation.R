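#' Initial membrane segmentation of a single-cell movie
#'
#' Deterministic candidate-membrane mask from the time-averaged image:
#' background-subtracted pixels above an intensity fraction of the maximum,
#' intersected with an annulus around the intensity-weighted centroid whose
#' radius and width are estimated from the radial distribution of the bright
#' pixels (membrane-labelled somata image as rings).
#'
#' @param movie A `vi_movie` (or plain 3D array).
#' @param intensity_frac Intensity threshold as a fraction of the
#'   background-subtracted maximum.
#' @param band_mult Half-width of the annulus band, as a multiple of the
#'   median absolute deviation of the bright-pixel radii.
#' @return Logical matrix mask.
#' @export
initial_segmentation <- function(movie, intensity_frac = 0.25,
                                 band_mult = 2.5) {
  data <- if (inherits(movie, "vi_movie")) movie$data else movie
  img <- rowMeans(array(data, c(dim(data)[1] * dim(data)[2], dim(data)[3])),
                  dims = 1)
  img <- matrix(img, dim(data)[1], dim(data)[2])
  bg <- stats::median(img)
  sig <- img - bg
  noise <- stats::mad(img)
  if (max(sig) <= 5 * max(noise, 1e-9))
    stop("no pixels above background; segmentation found no cell")
  cand <- sig > intensity_frac * max(sig)
  ys <- seq_len(nrow(img)); xs <- seq_len(ncol(img))
  w <- sig * cand
  cy <- sum(rowSums(w) * ys) / sum(w)
  cx <- sum(colSums(w) * xs) / sum(w)
  R <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  r_hat <- stats::median(R[cand])
  band <- max(band_mult * stats::mad(R[cand]), 2)
  mask <- cand & abs(R - r_hat) <= band
  if (!any(mask)) stop("segmentation produced an empty mask")
  mask
}

#' Regression-based pixel weighting
#'
#' Regresses every ROI pixel's time series on the mean fluorescence trace of
#' the initial segmentation; the regression slope is the pixel's weight
#' (negative slopes are clipped to zero - anticorrelated pixels are
#' background), and the retained support is the upper half of the positive
#' weights, which concentrates the mask on the most voltage-responsive
#' membrane and roughly halves the pixel count.
#'
#' @param movie A `vi_movie` or 3D array.
#' @param initial_mask Logical matrix from [initial_segmentation()].
#' @param support_quantile Quantile of positive weights retained.
#' @return An object of class `weight_mask`: `weights` (matrix, >= 0),
#'   `support` (logical matrix), `n_pixels_initial`, `n_pixels_final`.
#' @export
regression_weight_mask <- function(movie, initial_mask,
                                   support_quantile = 0.5) {
  data <- if (inherits(movie, "vi_movie")) movie$data else movie
  stopifnot(any(initial_mask), dim(data)[3] >= 100)
  d <- dim(data)
  flat <- array(data, c(d[1] * d[2], d[3]))
  m <- colMeans(flat[which(initial_mask), , drop = FALSE])
  mc <- m - mean(m)
  denom <- sum(mc^2)
  if (denom < 1e-12 * length(m))
    stop(paste("mean trace has no temporal structure; use a segment",
               "containing a stimulus"))
  # slope_i = sum((p_i - mean(p_i)) * mc) / sum(mc^2); the pixel-mean term
  # drops because mc sums to zero
  slopes <- as.vector(flat %*% mc) / denom
  w <- pmax(matrix(slopes, d[1], d[2]), 0)
  win <- w[initial_mask]
  thr <- stats::quantile(win[win > 0], support_quantile, names = FALSE)
  support <- initial_mask & w >= thr & w > 0
  structure(list(weights = w * support, support = support,
                 n_pixels_initial = sum(initial_mask),
                 n_pixels_final = sum(support)),
            class = "weight_mask")
}
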