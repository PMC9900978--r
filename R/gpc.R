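#' Generalized phase contrast spot synthesis
#'
#' Propagates the illuminated pi-disk mask through the 4f phase-contrast
#' stage: Fourier transform by the first lens, a pi phase shift applied to
#' the spatial-frequency components falling inside the phase-contrast filter
#' (PCF), and a second Fourier transform to the image plane. The
#' self-interference of the shifted low-frequency "synthetic reference wave"
#' with the rest of the beam converts the phase disk into a quasi-flat-top
#' intensity spot of the demagnified disk size.
#'
#' @param mask A [phase_mask()] (typically from [make_gpc_mask()]).
#' @param pcf_radius Physical PCF radius (um) in the Fourier plane.
#' @param fourier_focal Focal length (mm) of the transform lens, which sets
#'   the frequency-to-position scale of the Fourier plane.
#' @param input_profile Optional amplitude matrix on the padded working grid;
#'   defaults to the geometry's Gaussian illumination clipped to the panel.
#' @return An [excitation_map()] at `pitch / demag` um sampling carrying the
#'   complex image-plane field; attribute `throughput` is the fraction of
#'   input power delivered inside the target disk (when the mask is a binary
#'   pi-disk), attribute `energy_in`/`energy_out` the Parseval bookkeeping.
#' @export
gpc_synthesize <- function(mask, pcf_radius = 60, fourier_focal = 400,
                           input_profile = NULL) {
  stopifnot(inherits(mask, "phase_mask"), pcf_radius > 0)
  geom <- mask$geometry
  npad <- pad_size(geom)
  A <- if (is.null(input_profile)) slm_illumination(geom, npad)$amp
       else input_profile
  stopifnot(nrow(A) == npad, ncol(A) == npad)
  phi <- embed_phase(mask$phase, geom, npad)
  field <- A * exp(1i * phi)
  Ff <- cfft2(field)
  lam <- geom$wavelength / 1000                 # um
  f_um <- fourier_focal * 1000
  nu <- centered_freqs(npad, geom$pitch)
  NU <- matrix(nu, npad, npad)
  rf <- lam * f_um * sqrt(NU^2 + t(NU)^2)       # physical Fourier-plane radius
  if (pcf_radius > max(rf))
    stop("pcf_radius exceeds the extent of the frequency grid")
  Ff <- Ff * ifelse(rf <= pcf_radius, exp(1i * pi), 1)
  out <- cifft2(Ff)                             # image plane, centered
  I <- Mod(out)^2
  ds <- geom$pitch / geom$demag
  m <- excitation_map(I, ds, field = out)
  # throughput into the nominal disk (disk radius from the pi-area of the mask)
  a_pi <- sum(abs(mask$phase - pi) < 1e-6)
  if (a_pi > 0) {
    r_sample <- sqrt(a_pi / pi) * geom$pitch / geom$demag
    xs <- centered_coords(npad, ds)
    XS <- matrix(xs, npad, npad)
    inside <- XS^2 + t(XS)^2 <= r_sample^2
    attr(m, "throughput") <- sum(I[inside]) / sum(Mod(field)^2)
  }
  attr(m, "energy_in") <- sum(Mod(field)^2)
  attr(m, "energy_out") <- sum(I)
  m
}

#' Expanded-and-cropped Gaussian flat-top spot
#'
#' Models low-NA Gaussian illumination made quasi-uniform by expanding the
#' beam and cropping it to the target diameter: the waist is chosen so the
#' intensity at the crop edge is `uniformity` times the peak, and the
#' throughput is the fraction of the expanded beam's power inside the crop,
#' `1 - uniformity` for a Gaussian (the analytic power integral).
#'
#' @param target_diameter Spot diameter (um).
#' @param uniformity Required min/max intensity ratio over the spot, in (0,1).
#' @param pixel_size Sampling of the returned map (um).
#' @return List with `map` (an [excitation_map()]) and `throughput`.
#' @export
gaussian_flattop_spot <- function(target_diameter = 12, uniformity = 0.9,
                                  pixel_size = 0.25) {
  stopifnot(target_diameter > 0)
  if (!(uniformity > 0 && uniformity < 1))
    stop("uniformity must lie strictly between 0 and 1")
  r <- target_diameter / 2
  w <- r * sqrt(2 / log(1 / uniformity))        # exp(-2 r^2/w^2) = uniformity
  n <- floor(2 * target_diameter / pixel_size / 2) * 2
  x <- centered_coords(n, pixel_size)
  X <- matrix(x, n, n)
  R2 <- X^2 + t(X)^2
  I <- ifelse(R2 <= r^2, exp(-2 * R2 / w^2), 0)
  list(map = excitation_map(I, pixel_size),
       throughput = 1 - uniformity)
}
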