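#' Render an aggregate fluorescence trace without a camera frame
#'
#' Photon-level forward model of the summed membrane fluorescence of one
#' cell: per frame the expected photon count is
#' `f0_photons * (P/Pref)^2 * (1 + dFF) * bleach * lit`, Poisson-distributed,
#' plus Gaussian aggregate read noise. Equivalent to summing a rendered
#' movie over its membrane mask, at a fraction of the cost; used for long
#' recordings (spike trains, spontaneous activity, all-optical scans) where
#' per-pixel rendering adds nothing to the analysis under test.
#'
#' @param protocol A [make_protocol()] result.
#' @param f0_photons Expected baseline photons per frame over the cell mask
#'   at `reference_density`.
#' @param sensor A [sensor_model()].
#' @param seed Integer seed.
#' @param power_density,reference_density Power scaling as in
#'   [render_movie()].
#' @param exposure,readout Frame timing (ms).
#' @param read_sd Aggregate Gaussian read-noise s.d. (counts per frame).
#' @param voltage Optional replacement voltage command (mV).
#' @return A `vi_trace` (raw photons per frame) ready for [detrend_dff()];
#'   attribute `truth` holds the frame-integrated noiseless dF/F and event
#'   times.
#' @export
render_trace <- function(protocol, f0_photons, sensor = sensor_model(),
                         seed = 1L, power_density = 1.33,
                         reference_density = 1.33, exposure = NULL,
                         readout = 0.02, read_sd = 2, voltage = NULL) {
  if (is.null(exposure)) exposure <- 1000 / protocol$acquisition_rate - readout
  tt <- protocol$time; dt <- protocol$dt
  duration <- tt[length(tt)] + dt / 2
  fp <- exposure + readout
  n_frames <- floor(duration / fp)
  frame_start <- (seq_len(n_frames) - 1) * fp
  i0 <- pmin(ceiling(frame_start / dt + 0.5 - 1e-9) - 1, length(tt))
  i1 <- pmin(ceiling((frame_start + exposure) / dt + 0.5 - 1e-9) - 1,
             length(tt))
  nw <- pmax(i1 - i0, 1L)
  win_mean <- function(x) {
    cs <- c(0, cumsum(x))
    (cs[i1 + 1] - cs[i0 + 1]) / nw
  }
  lit_ms <- win_mean(protocol$gate) * nw * dt
  bleach <- bleach_factors(lit_ms, sensor, power_density)
  v <- if (is.null(voltage)) protocol$command else voltage
  dff <- voltage_to_dff(v, dt, sensor, protocol$v_rest)
  dff_f <- win_mean(dff)
  pscale <- (power_density / reference_density)^2
  lam <- f0_photons * pscale * pmax(1 + dff_f, 0) * bleach *
    (lit_ms / exposure)
  raw <- with_seed(seed,
    stats::rpois(n_frames, lam) + stats::rnorm(n_frames, 0, read_sd))
  tr <- structure(list(time = frame_start, raw_f = raw,
                       lit = lit_ms / exposure >= 0.999,
                       epochs = protocol$epochs, frame_period = fp,
                       baseline = NULL, f0 = NULL, dff = NULL),
                  class = "vi_trace")
  attr(tr, "truth") <- list(dff = dff_f, events = protocol$events,
                            bleach = bleach)
  tr
}
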