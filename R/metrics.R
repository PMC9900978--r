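#' Empirical and shot-noise SNR of a step response
#'
#' The empirical SNR is the response amplitude (mean |dF/F| over the
#' response window, relative to the baseline-window mean) divided by the
#' standard deviation of the baseline dF/F. The shot-noise SNR is
#' `(-dF/F0) * sqrt(F0)` with the baseline fluorescence converted to
#' detected photons via the camera gain and offset.
#'
#' @param trace A detrended trace.
#' @param response_window,baseline_window Frame-time windows (ms,
#'   two-element vectors); must not overlap.
#' @param gain Counts per photon.
#' @param offset Camera offset (counts) subtracted before the photon
#'   conversion.
#' @param n_px Number of pixels averaged into the trace; with `n_px` the
#'   photon count is the summed count over the support, which is what sets
#'   the shot-noise limit of the averaged trace.
#' @return List: `snr_empirical`, `snr_shot`, `dff_amp` (-dF/F, positive),
#'   `f0_photons`.
#' @export
snr_metrics <- function(trace, response_window, baseline_window, gain = 1,
                        offset = 0, n_px = 1) {
  stopifnot(!is.null(trace$dff))
  rw <- trace$time >= response_window[1] & trace$time < response_window[2] &
    !is.na(trace$dff)
  bw <- trace$time >= baseline_window[1] & trace$time < baseline_window[2] &
    !is.na(trace$dff)
  if (response_window[1] < baseline_window[2] &&
      baseline_window[1] < response_window[2])
    stop("response and baseline windows overlap")
  stopifnot(sum(rw) >= 1, sum(bw) >= 2)
  base_sd <- stats::sd(trace$dff[bw])
  if (base_sd <= 0) stop("baseline has zero variance")
  amp <- abs(mean(trace$dff[rw]) - mean(trace$dff[bw]))
  f0_counts <- mean(trace$raw_f[bw]) - offset
  f0_photons <- max(f0_counts, 0) / gain * n_px
  list(snr_empirical = amp / base_sd,
       snr_shot = amp * sqrt(f0_photons),
       dff_amp = amp, f0_photons = f0_photons)
}

#' Photostability of a fluorescence trace
#'
#' Ratio of the integral of the baseline (non-response) fluorescence to
#' `F0 * n_t`, where `F0` is the fluorescence in the first illuminated
#' frame and `n_t` the number of baseline timepoints; 1 means no bleaching.
#' Computed on the raw trace - detrending does not affect it.
#'
#' @param trace A trace (detrended or not).
#' @param baseline_frames Logical vector marking non-response frames;
#'   defaults to all illuminated frames.
#' @return Photostability fraction.
#' @export
photostability <- function(trace, baseline_frames = NULL) {
  if (is.null(baseline_frames)) baseline_frames <- trace$lit
  f <- trace$raw_f[baseline_frames]
  if (length(f) < 2) stop("need at least two baseline frames")
  f0 <- f[1]
  if (f0 <= 0) stop("F0 must be positive")
  sum(f) / (f0 * length(f))
}

#' Photorecovery across illumination epochs
#'
#' Ratio of the pre-step fluorescence in each illumination epoch to that of
#' the first epoch; recovery of 1 means the dark interval fully restored
#' the fluorescence.
#'
#' @param trace A trace.
#' @param prestep_ms Length (ms) of the pre-step window at the start of each
#'   epoch.
#' @return List: `ratios` (per epoch, first = 1), `mean_recovery` (mean over
#'   epochs 2..K).
#' @export
photorecovery <- function(trace, prestep_ms = 50) {
  ep <- trace$epochs
  if (nrow(ep) < 2) stop("photorecovery needs at least two illumination epochs")
  pre <- vapply(seq_len(nrow(ep)), function(k) {
    idx <- trace$time >= ep$start[k] & trace$time < ep$start[k] + prestep_ms
    mean(trace$raw_f[idx])
  }, numeric(1))
  ratios <- pre / pre[1]
  list(ratios = ratios, mean_recovery = mean(ratios[-1]))
}

#' Power-response fits
#'
#' Quantifies the excitation-power dependence of a power series:
#' the log-log slope of baseline fluorescence versus power density (2 for
#' unsaturated two-photon excitation), the ordinary-least-squares `r^2` of
#' SNR versus power density (near 1 in the shot-noise-limited regime), and
#' the sign of the `-dF/F0` trend.
#'
#' @param series Data frame with columns `power_density`, `f0`, `snr`, and
#'   optionally `dff` (one row per power level; average cells first).
#' @return List: `f0_power_exponent`, `snr_power_r2`, `snr_fit`
#'   (intercept/slope), `dff_trend` (-1, 0 or 1).
#' @export
fit_power_response <- function(series) {
  stopifnot(is.data.frame(series), nrow(series) >= 3,
            all(c("power_density", "f0", "snr") %in% names(series)))
  if (any(series$f0 <= 0)) stop("baseline fluorescence must be positive")
  lf <- stats::lm(log(f0) ~ log(power_density), data = series)
  ls <- stats::lm(snr ~ power_density, data = series)
  # r^2 computed directly (summary.lm warns on noise-free synthetic series)
  r2 <- 1 - sum(stats::resid(ls)^2) /
    sum((series$snr - mean(series$snr))^2)
  dff_trend <- if (!is.null(series$dff))
    sign(stats::coef(stats::lm(dff ~ power_density, data = series))[2])
  else NA_real_
  list(f0_power_exponent = unname(stats::coef(lf)[2]),
       snr_power_r2 = r2,
       snr_fit = unname(stats::coef(ls)),
       dff_trend = unname(dff_trend))
}

#' Effective resolution from a displacement scan
#'
#' FWHM of the normalised response (e.g. spike `-dF/F0`) versus
#' excitation-spot displacement, by linear interpolation of the half-maximum
#' crossings.
#'
#' @param displacement Displacements (um), spanning beyond half maximum on
#'   both sides.
#' @param response Response at each displacement.
#' @return FWHM (um).
#' @export
resolution_curve <- function(displacement, response) {
  o <- order(displacement)
  x <- displacement[o]; y <- response[o]
  y <- y / max(y)
  if (sum(y >= 0.5) == 1) return(stats::median(diff(x)))  # delta-like
  fwhm_1d(x, y)
}
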