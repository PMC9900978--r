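#' Propagate a focal field into a z-stack
#'
#' Band-limited angular-spectrum propagation of a synthesized focal field
#' over a set of axial planes, with an optional spectral temporal-focusing
#' model. The pulse spectrum is discretised into
#' `train$spectral_samples` Gaussian-weighted components (spectral FWHM from
#' the transform-limited pulse duration); the grating disperses each
#' component so that away from focus component k is laterally displaced by
#' `z * tan(theta_k)`, with `theta_k` from the grating equation scaled by the
#' relay's angular magnification. At each plane the two-photon rate is
#' computed coherently per pixel as `sum_t |E(t)|^4` over the reconstructed
#' pulse (components in phase at the focus), which captures the loss of
#' pulse compression - and hence of two-photon efficiency - away from the
#' temporal-focusing plane. With `spectral_samples = 1` this reduces to
#' ordinary monochromatic propagation.
#'
#' @param input An [excitation_map()] carrying a complex `field` (e.g. from
#'   [gpc_synthesize()] or [reconstruct_hologram()]) or a [phase_mask()]
#'   (reconstructed as a hologram).
#' @param train An [optical_train()].
#' @param z Vector of axial positions (um); a symmetric range about 0 is
#'   recommended.
#' @param crop Side length (pixels) of the centered sub-field to propagate;
#'   keeps the cost manageable for confined spots. `NULL` for the full grid.
#' @param wavelength Center wavelength (um); defaults to the mask geometry's.
#' @return A 3D [excitation_map()]: `intensity[x, y, iz]` is the
#'   time-averaged intensity, `two_photon[x, y, iz]` the normalised
#'   two-photon excitation rate. A warning is emitted if the z sampling is
#'   coarser than a quarter of the measured axial FWHM.
#' @export
propagate_stack <- function(input, train = optical_train(), z,
                            crop = 256L, wavelength = NULL) {
  if (inherits(input, "phase_mask")) {
    if (is.null(wavelength)) wavelength <- input$geometry$wavelength / 1000
    input <- reconstruct_hologram(input)
  }
  stopifnot(inherits(input, "excitation_map"), !is.null(input$field))
  if (is.null(wavelength)) wavelength <- 0.940
  fld <- input$field
  ds <- input$pixel_size
  if (!is.null(crop) && crop < nrow(fld)) fld <- crop_center(fld, crop)
  n <- nrow(fld)
  P <- 2L * n                                   # zero-padded working grid
  fp <- matrix(0 + 0i, P, P)
  fp[seq_len(n) + n / 2, seq_len(n) + n / 2] <- fld
  FP <- cfft2(fp)
  nu <- centered_freqs(P, ds)
  NU <- matrix(nu, P, P)
  k2 <- (1 / wavelength)^2 - NU^2 - t(NU)^2
  # band limit: evanescent waves and frequencies beyond the objective NA
  na_lim <- train$objective_na / wavelength
  pm <- k2 > 0 & (NU^2 + t(NU)^2) <= na_lim^2
  kz <- sqrt(pmax(k2, 0))
  K <- train$spectral_samples
  if (K > 1) {
    # Gaussian pulse spectrum: intensity FWHM in wavelength units
    c_umps <- 299792458e6 * 1e-15               # um per fs
    dl_fwhm <- 0.441 * wavelength^2 / (c_umps * train$pulse_duration)
    sig <- dl_fwhm / (2 * sqrt(2 * log(2)))
    dls <- seq(-2.5 * sig, 2.5 * sig, length.out = K)
    amp <- exp(-dls^2 / (4 * sig^2))            # amplitude spectrum
    amp <- amp / sqrt(sum(amp^2))
    theta <- train$angle_mag * (train$grating_density / 1000) * dls
  } else {
    dls <- 0; amp <- 1; theta <- 0
  }
  nz <- length(z)
  cidx <- seq_len(n) + n / 2
  I3 <- array(0, c(n, n, nz))
  T3 <- array(0, c(n, n, nz))
  for (iz in seq_len(nz)) {
    H <- ifelse(pm, exp(2i * pi * z[iz] * kz), 0)
    base <- FP * H
    if (K > 1) {
      Ek <- matrix(0 + 0i, P * P, K)
      for (k in seq_len(K)) {
        shift <- exp(-2i * pi * NU * (z[iz] * tan(theta[k])))
        Ek[, k] <- amp[k] * as.vector(cifft2(base * shift))
      }
      Isum <- matrix(rowSums(Mod(Ek)^2), P, P)
      Et <- stats::mvfft(t(Ek))                 # pulse time samples per pixel
      tp <- matrix(colSums(Mod(Et)^4) / K, P, P)
    } else {
      f0 <- cifft2(base)
      Isum <- Mod(f0)^2
      tp <- Isum^2
    }
    I3[, , iz] <- Isum[cidx, cidx]
    T3[, , iz] <- tp[cidx, cidx]
  }
  zs <- if (nz > 1) stats::median(diff(z)) else NA_real_
  out <- excitation_map(I3, ds, z_step = zs, z = z)
  out$two_photon <- T3 / max(T3)
  if (nz > 2) {
    ax <- apply(out$two_photon, 3, sum)
    fw <- tryCatch(fwhm_1d(z, ax), error = function(e) NA_real_)
    if (!is.na(fw) && zs > fw / 4)
      warning(sprintf("z step %.3g um is coarser than axial FWHM/4 (%.3g um)",
                      zs, fw / 4))
  }
  out
}

#' Two-photon map and speckle statistics
#'
#' Squares an intensity pattern (normalised to peak 1) and computes the
#' speckle enhancement `<I^2>/<I>^2` over the spot support, defined as the
#' pixels whose intensity exceeds 10% of the spot mean (the mean over pixels
#' above half maximum), which excludes dilution by dark surround and soft
#' edges. The enhancement is 1 for a uniform spot and 2 for fully developed
#' (circular-Gaussian) speckle.
#'
#' @param map An [excitation_map()] (2D, or 3D: the central plane is used for
#'   the statistics).
#' @return List with `map` (two-photon updated) and `metrics`, a
#'   [beam_metrics()]-style list containing `speckle_enhancement`.
#' @export
two_photon_map <- function(map) {
  stopifnot(inherits(map, "excitation_map"))
  I <- map$intensity
  if (length(dim(I)) == 3) I <- I[, , ceiling(dim(I)[3] / 2)]
  core <- I >= max(I) / 2
  sup <- I > 0.1 * mean(I[core])
  enh <- mean(I[sup]^2) / mean(I[sup])^2
  list(map = map,
       metrics = list(speckle_enhancement = enh,
                      support_pixels = sum(sup),
                      integrated_two_photon = sum(I^2) / sum(I)^2))
}

#' Beam metrics of an excitation pattern
#'
#' Lateral (and for stacks, axial) full width at half maximum of the
#' two-photon excitation profile. Lateral profiles are taken through the
#' intensity-weighted centroid of the focal plane, with the half-maximum
#' crossings located by linear interpolation; the axial profile is the
#' plane-integrated two-photon signal.
#'
#' @param map An [excitation_map()].
#' @return List with `lateral_fwhm` (mean of the row/column profiles, plus
#'   `lateral_fwhm_x`, `lateral_fwhm_y`), `axial_fwhm` (um, `NA` for single
#'   planes), `speckle_enhancement`, and `throughput` when the map carries
#'   one.
#' @export
beam_metrics <- function(map) {
  stopifnot(inherits(map, "excitation_map"))
  tp <- map$two_photon
  is3d <- length(dim(tp)) == 3
  plane <- if (is3d) {
    iz0 <- which.min(abs(map$z))
    tp[, , iz0]
  } else tp
  xs <- centered_coords(nrow(plane), map$pixel_size)
  wsum <- sum(plane)
  cy <- sum(rowSums(plane) * xs) / wsum
  cx <- sum(colSums(plane) * xs) / wsum
  iy <- which.min(abs(xs - cy)); ix <- which.min(abs(xs - cx))
  fx <- fwhm_1d(xs, plane[iy, ])
  fy <- fwhm_1d(xs, plane[, ix])
  ax <- if (is3d) fwhm_1d(map$z, apply(tp, 3, sum)) else NA_real_
  enh <- two_photon_map(map)$metrics$speckle_enhancement
  list(lateral_fwhm = (fx + fy) / 2, lateral_fwhm_x = fx, lateral_fwhm_y = fy,
       axial_fwhm = ax, speckle_enhancement = enh,
       throughput = attr(map, "throughput"))
}
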