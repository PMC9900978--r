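#' Spatial light modulator geometry
#'
#' Describes the phase-modulating device on which masks are displayed and its
#' mapping to the sample plane. Defaults correspond to a 600 x 800 pixel,
#' 20 um pitch LCOS device addressed at 940 nm, relayed to the sample with a
#' total lateral demagnification of 80 (Fourier/tube lens chain 400/300 mm to
#' the grating-conjugate plane, then 300 mm tube lens onto a 5 mm focal,
#' 0.8 NA objective).
#'
#' @param n_rows,n_cols SLM pixel counts.
#' @param pitch SLM pixel pitch (um).
#' @param wavelength Excitation wavelength (nm).
#' @param aperture_radius Usable aperture radius at the SLM (um). Defaults to
#'   half the short side of the panel.
#' @param demag Lateral demagnification from the SLM plane to the sample
#'   plane; the sample-plane pixel of synthesized fields is `pitch / demag`.
#' @param beam_waist 1/e^2 amplitude waist (um) of the expanded Gaussian beam
#'   illuminating the SLM.
#' @return An object of class `slm_geometry`.
#' @export
slm_geometry <- function(n_rows = 600L, n_cols = 800L, pitch = 20,
                         wavelength = 940, aperture_radius = NULL,
                         demag = 80, beam_waist = 3500) {
  stopifnot(n_rows > 0, n_cols > 0, pitch > 0, wavelength > 0, demag > 0,
            beam_waist > 0)
  if (is.null(aperture_radius))
    aperture_radius <- min(n_rows, n_cols) / 2 * pitch
  stopifnot(aperture_radius > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch = pitch, wavelength = wavelength,
                 aperture_radius = aperture_radius, demag = demag,
                 beam_waist = beam_waist),
            class = "slm_geometry")
}

#' Optical train for propagation and temporal focusing
#'
#' Lens chain and dispersion parameters used when propagating synthesized
#' fields away from focus. `spectral_samples = 1` disables temporal focusing
#' (a single monochromatic component). The angular magnification applied to
#' the grating dispersion is the inverse of the grating-to-sample lateral
#' magnification (default 60 = 300 mm tube / 5 mm objective).
#'
#' @param focal_lengths Ordered relay focal lengths (mm); kept for the record.
#' @param objective_focal Objective focal length (mm).
#' @param objective_na Objective numerical aperture, in (0, 1].
#' @param grating_density Diffraction-grating groove density (lines/mm).
#' @param pulse_duration Transform-limited pulse duration (fs).
#' @param spectral_samples Number of discrete spectral components (>= 1).
#' @param angle_mag Angular magnification from grating plane to sample plane.
#' @return An object of class `optical_train`.
#' @export
optical_train <- function(focal_lengths = c(400, 300, 500, 500, 300),
                          objective_focal = 5, objective_na = 0.8,
                          grating_density = 600, pulse_duration = 100,
                          spectral_samples = 11L, angle_mag = 60) {
  stopifnot(objective_na > 0, objective_na <= 1, grating_density > 0,
            pulse_duration > 0, spectral_samples >= 1)
  structure(list(focal_lengths = focal_lengths,
                 objective_focal = objective_focal,
                 objective_na = objective_na,
                 grating_density = grating_density,
                 pulse_duration = pulse_duration,
                 spectral_samples = as.integer(spectral_samples),
                 angle_mag = angle_mag),
            class = "optical_train")
}

#' Excitation spot specification
#'
#' @param center_xyz Sample-plane coordinates (um), z = 0 at the objective
#'   focus.
#' @param diameter Spot diameter (um).
#' @param weight Relative intensity target for multi-spot holograms.
#' @return An object of class `spot_spec`.
#' @export
spot_spec <- function(center_xyz = c(0, 0, 0), diameter = 12, weight = 1) {
  if (length(center_xyz) == 2) center_xyz <- c(center_xyz, 0)
  stopifnot(length(center_xyz) == 3, diameter >= 0, weight > 0)
  structure(list(center_xyz = center_xyz, diameter = diameter,
                 weight = weight),
            class = "spot_spec")
}

#' Effective camera frame rate
#'
#' sCMOS acquisition alternates exposure and row readout, so the effective
#' rate is `1 / (exposure + readout)`; a 1 ms exposure with 0.02 ms readout
#' yields 980 Hz.
#'
#' @param exposure_ms Exposure time (ms).
#' @param readout_ms Readout dead time (ms).
#' @return Frame rate in Hz.
#' @export
effective_frame_rate <- function(exposure_ms, readout_ms = 0.02) {
  stopifnot(exposure_ms > 0, readout_ms >= 0)
  1000 / (exposure_ms + readout_ms)
}

#' Field-of-view extent from camera row count
#'
#' @param n_rows Number of camera rows read out.
#' @param pixel_size Sample-plane pixel size (um), default 0.1625.
#' @return Extent in um.
#' @export
fov_extent <- function(n_rows, pixel_size = 0.1625) {
  stopifnot(n_rows > 0, pixel_size > 0)
  n_rows * pixel_size
}

#' Average power delivered to one cell-sized spot
#'
#' Converts an excitation power density into power per cell for a circular
#' spot, `density * pi * (diameter/2)^2`, reported to the nearest
#' `round_to` mW (the reporting convention used for soma-sized spots; set
#' `round_to = NULL` for the raw value).
#'
#' @param power_density Power density (mW/um^2).
#' @param diameter Spot diameter (um).
#' @param round_to Rounding quantum in mW, or `NULL`.
#' @return Power in mW.
#' @export
power_per_cell <- function(power_density, diameter = 12, round_to = 5) {
  stopifnot(power_density >= 0, diameter > 0)
  p <- power_density * pi * (diameter / 2)^2
  if (!is.null(round_to)) p <- round(p / round_to) * round_to
  p
}
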