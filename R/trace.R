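#' Extract a fluorescence trace from a movie
#'
#' Weighted (or uniform) mean of the ROI pixels per frame. Weights are
#' normalised, so rescaling all weights leaves the trace unchanged.
#'
#' @param movie A `vi_movie` or 3D array.
#' @param weights A [regression_weight_mask()] result, a numeric matrix, a
#'   logical mask (uniform over the mask), or `NULL` (uniform over the
#'   frame).
#' @param truth Optional `ground_truth` supplying frame times and
#'   illumination epochs; otherwise taken from the movie metadata.
#' @param subtract_offset Subtract the camera offset recorded in the movie's
#'   acquisition settings (required for meaningful dF/F).
#' @return An object of class `vi_trace`: `time` (frame start, ms), `raw_f`
#'   (offset-corrected counts), `lit` (logical), `epochs`, and empty
#'   `baseline`/`dff` slots until [detrend_dff()] is applied.
#' @export
extract_trace <- function(movie, weights = NULL, truth = NULL,
                          subtract_offset = TRUE) {
  data <- if (inherits(movie, "vi_movie")) movie$data else movie
  d <- dim(data)
  w <- if (is.null(weights)) matrix(1, d[1], d[2])
  else if (inherits(weights, "weight_mask")) weights$weights
  else if (is.logical(weights)) weights + 0
  else weights
  stopifnot(all(dim(w) == d[1:2]), all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  flat <- array(data, c(d[1] * d[2], d[3]))
  raw <- as.vector(crossprod(flat, as.vector(w)))
  if (subtract_offset && inherits(movie, "vi_movie"))
    raw <- raw - movie$acq$offset
  fp <- if (inherits(movie, "vi_movie")) movie$meta$frame_period else 1
  tm <- (seq_len(d[3]) - 1) * fp
  lit <- if (!is.null(truth)) truth$lit else rep(TRUE, d[3])
  epochs <- if (!is.null(truth)) truth$epochs else
    data.frame(start = 0, end = tm[length(tm)] + fp)
  structure(list(time = tm, raw_f = raw, lit = lit, epochs = epochs,
                 frame_period = fp, baseline = NULL, f0 = NULL, dff = NULL),
            class = "vi_trace")
}

#' @export
print.vi_trace <- function(x, ...) {
  cat(sprintf("<vi_trace> %d frames, %.4g ms/frame%s\n", length(x$raw_f),
              x$frame_period,
              if (!is.null(x$dff)) ", detrended" else ""))
  invisible(x)
}

#' Detrend a trace and compute dF/F
#'
#' Fits a baseline to the illuminated frames of each epoch and normalises:
#' `dff = (raw - baseline) / baseline`. The default baseline is a
#' bi-exponential fit (photobleaching model) on event-masked frames, with
#' automatic fallback to a single exponential, and to a running-percentile
#' filter if the fits fail; `method = "percentile"` forces the filter.
#' Candidate response frames (robust outliers from a running median, plus
#' `event_pad_ms` of margin) are excluded from the fits so the baseline is
#' not biased by responses. `raw_f` is never modified.
#'
#' @param trace A [extract_trace()] result.
#' @param method "biexp" or "percentile".
#' @param percentile Percentile for the filter fallback.
#' @param window_frames Window of the percentile filter.
#' @param event_pad_ms Margin (ms) around detected candidate events masked
#'   from baseline fits.
#' @param f0_mode "epoch_start" (baseline at each epoch's first lit frame)
#'   or "global" (first epoch's value) for the stored `f0`.
#' @return The trace with `baseline`, `dff`, `f0` filled in; `dff` is `NA`
#'   outside illumination epochs.
#' @export
detrend_dff <- function(trace, method = c("biexp", "percentile"),
                        percentile = 0.5, window_frames = 51,
                        event_pad_ms = 10, f0_mode = "epoch_start") {
  method <- match.arg(method)
  raw <- trace$raw_f
  n <- length(raw)
  baseline <- rep(NA_real_, n)
  lit <- trace$lit
  pad <- ceiling(event_pad_ms / trace$frame_period)
  runs <- rle(lit)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  f0 <- NA_real_
  n_fallback <- 0L
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    y <- raw[idx]
    keep <- !flag_events(y, pad)
    bl <- NULL
    if (method == "biexp" && sum(keep) >= 8) {
      bl <- fit_bleach_baseline(seq_along(y), y, keep)
      if (is.null(bl)) n_fallback <- n_fallback + 1L
    }
    if (is.null(bl)) bl <- percentile_baseline(y, keep, percentile,
                                               window_frames)
    baseline[idx] <- bl
    if (is.na(f0)) f0 <- bl[1]
  }
  if (n_fallback > 0)
    warning(sprintf("baseline fit failed in %d epoch(s); percentile filter used",
                    n_fallback))
  trace$baseline <- baseline
  trace$f0 <- f0
  trace$dff <- (raw - baseline) / baseline
  trace$dff[!lit] <- NA_real_
  trace
}

# Robust flag of candidate response frames (TRUE = masked). A first-pass
# bleach-model fit on all frames provides the trend; frames falling more
# than 4 noise-sigmas BELOW it are flagged (the indicator is negative-going,
# so responses dip under the baseline while the pass-1 fit, being monotone,
# cannot chase them). Falls back to a running median for short epochs.
flag_events <- function(y, pad) {
  n <- length(y)
  s <- stats::mad(diff(y)) / sqrt(2)
  if (!is.finite(s) || s <= 0) return(rep(FALSE, n))
  trend <- if (n >= 12) fit_bleach_baseline(seq_len(n), y, rep(TRUE, n))
  if (is.null(trend))
    trend <- stats::runmed(y, k = min(31, 2 * (n %/% 2) - 1))
  ev <- (trend - y) > 4 * s
  if (pad > 0 && any(ev)) {
    idx <- which(ev)
    for (i in idx) ev[max(1, i - pad):min(n, i + pad)] <- TRUE
  }
  ev
}

# bi-exponential (falling back to single-exponential) baseline fit
fit_bleach_baseline <- function(x, y, keep) {
  xf <- x[keep]; yf <- y[keep]
  y0 <- max(mean(yf[seq_len(min(5, length(yf)))]), 1e-6)
  span <- max(x) - min(x) + 1
  fit2 <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      yf ~ c0 + a1 * exp(-xf / t1) + a2 * exp(-xf / t2),
      start = list(c0 = min(yf), a1 = 0.1 * y0, t1 = span / 5,
                   a2 = max(mean(yf) - min(yf), 1e-3), t2 = span * 2),
      lower = c(0, 0, 1, 0, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (!is.null(fit2)) {
    p <- stats::coef(fit2)
    return(p["c0"] + p["a1"] * exp(-x / p["t1"]) +
             p["a2"] * exp(-x / p["t2"]))
  }
  fit1 <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(yf ~ c0 + a1 * exp(-xf / t1),
                      start = list(c0 = min(yf), a1 = max(y0 - min(yf), 1e-3),
                                   t1 = span),
                      lower = c(0, 0, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (!is.null(fit1)) {
    p <- stats::coef(fit1)
    return(p["c0"] + p["a1"] * exp(-x / p["t1"]))
  }
  NULL
}

percentile_baseline <- function(y, keep, percentile, window) {
  n <- length(y)
  yk <- y
  yk[!keep] <- NA
  half <- window %/% 2
  out <- vapply(seq_len(n), function(i) {
    w <- yk[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_
    else stats::quantile(w, percentile, na.rm = TRUE, names = FALSE)
  }, numeric(1))
  # interpolate across stretches fully inside masked (response) regions
  if (anyNA(out)) {
    ok <- which(!is.na(out))
    if (length(ok) >= 2)
      out <- stats::approx(ok, out[ok], xout = seq_len(n), rule = 2)$y
    else out[is.na(out)] <- stats::median(y)
  }
  out
}
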