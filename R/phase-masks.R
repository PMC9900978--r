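#' Phase mask container
#'
#' A phase-only SLM pattern in radians, wrapped to `[0, 2*pi)`, with the
#' geometry it was computed for.
#'
#' @param phase Matrix of phases (radians), dimensions matching the geometry.
#' @param geometry An [slm_geometry()].
#' @return An object of class `phase_mask`.
#' @export
phase_mask <- function(phase, geometry) {
  stopifnot(inherits(geometry, "slm_geometry"),
            nrow(phase) == geometry$n_rows, ncol(phase) == geometry$n_cols)
  structure(list(phase = phase %% (2 * pi), geometry = geometry),
            class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf("<phase_mask> %d x %d px, pitch %.3g um\n",
              x$geometry$n_rows, x$geometry$n_cols, x$geometry$pitch))
  invisible(x)
}

#' Binary pi-disk mask for generalized phase contrast
#'
#' GPC shapes a flat-top spot by applying a pi phase shift to the part of the
#' beam overlapping a circular disk whose sample-plane diameter, mapped
#' through the relay demagnification, sets the SLM-plane disk radius.
#'
#' @param disk A [spot_spec()] giving the sample-plane spot.
#' @param geom An [slm_geometry()].
#' @return A [phase_mask()] with phases in `{0, pi}`.
#' @export
make_gpc_mask <- function(disk = spot_spec(), geom = slm_geometry()) {
  stopifnot(inherits(disk, "spot_spec"))
  r_slm <- disk$diameter / 2 * geom$demag
  if (r_slm > geom$aperture_radius)
    stop(sprintf(paste0("magnified disk radius %.1f um exceeds the SLM ",
                        "aperture radius %.1f um"),
                 r_slm, geom$aperture_radius))
  y <- centered_coords(geom$n_rows, geom$pitch) -
    disk$center_xyz[2] * geom$demag
  x <- centered_coords(geom$n_cols, geom$pitch) -
    disk$center_xyz[1] * geom$demag
  R2 <- outer(y^2, x^2, `+`)
  phase <- if (r_slm > 0) ifelse(R2 <= r_slm^2, pi, 0)
           else matrix(0, geom$n_rows, geom$n_cols)
  phase_mask(phase, geom)
}

#' Iterative Gerchberg-Saxton hologram
#'
#' Computes a phase-only hologram whose far-field reconstruction approximates
#' a target amplitude pattern. The SLM is treated as the Fourier conjugate of
#' the sample plane; the sample grid pixel is `pitch / demag` so the
#' addressable field matches the nominal excitation field of the relay. Each
#' iteration replaces the focal amplitude by the (energy-scaled) target
#' inside the target support and keeps the computed amplitude elsewhere, then
#' back-propagates and restores the illumination amplitude.
#'
#' @param target Nonnegative target amplitude. Either a matrix on the padded
#'   sample grid (centered) or a list of [spot_spec()]s, converted with
#'   [disk_target()].
#' @param geom An [slm_geometry()].
#' @param n_iter Number of iterations (>= 1).
#' @param seed Integer seed for the random initial phase.
#' @return A [phase_mask()]; attribute `history` holds the per-iteration
#'   Pearson correlation between reconstruction intensity and target support,
#'   attribute `npad` the working grid size.
#' @export
gs_hologram <- function(target, geom = slm_geometry(), n_iter = 50L,
                        seed = 1L) {
  stopifnot(n_iter >= 1)
  npad <- pad_size(geom)
  if (is.list(target) || inherits(target, "spot_spec"))
    target <- disk_target(target, geom, npad)
  stopifnot(is.matrix(target), nrow(target) == npad, ncol(target) == npad,
            all(target >= 0))
  if (all(target == 0)) stop("target amplitude is identically zero")
  ill <- slm_illumination(geom, npad)
  A <- ill$amp
  sup <- target > 0
  # scale target so its energy matches the FFT-domain input energy
  targ_s <- target * sqrt(sum(A^2) * length(A) / sum(target^2))
  tvec <- as.vector(target)
  phi <- with_seed(seed, matrix(stats::runif(npad^2, 0, 2 * pi), npad, npad))
  hist <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    Ff <- cfft2(A * exp(1i * phi))
    hist[it] <- stats::cor(as.vector(Mod(Ff)^2), tvec)
    newamp <- ifelse(sup, targ_s, Mod(Ff))
    back <- cifft2(newamp * exp(1i * Arg(Ff)))
    phi <- Arg(back)
  }
  mask <- phase_mask(phi[ill$rows, ill$cols], geom)
  attr(mask, "history") <- hist
  attr(mask, "npad") <- npad
  mask
}

#' Multi-spot hologram with per-spot weight equalisation
#'
#' Weighted Gerchberg-Saxton: after each iteration the target amplitude of
#' every spot is rescaled by the ratio of the mean achieved spot amplitude to
#' that spot's achieved amplitude (linear weight update), which equalises
#' (or, for unequal requested weights, proportions) the delivered intensity
#' across spots.
#'
#' @param spots List of [spot_spec()]s (1 to 100), centers within the
#'   addressable field.
#' @param geom An [slm_geometry()].
#' @param n_iter Iterations.
#' @param seed Integer seed for the initial phase.
#' @return A [phase_mask()]; attribute `history` as in [gs_hologram()],
#'   attribute `spot_weights` the final internal weights.
#' @export
weighted_gs_multiplex <- function(spots, geom = slm_geometry(),
                                  n_iter = 50L, seed = 1L) {
  if (inherits(spots, "spot_spec")) spots <- list(spots)
  stopifnot(length(spots) >= 1, length(spots) <= 100, n_iter >= 1)
  npad <- pad_size(geom)
  field_half <- npad * geom$pitch / geom$demag / 2
  for (s in spots)
    if (any(abs(s$center_xyz[1:2]) + s$diameter / 2 > field_half))
      stop("spot outside the addressable excitation field")
  if (length(spots) > 1) {
    ctr <- t(vapply(spots, function(s) s$center_xyz[1:2], numeric(2)))
    dmin <- min(stats::dist(ctr))
    if (dmin < max(vapply(spots, `[[`, numeric(1), "diameter")))
      warning("spots closer than one diameter; reconstructions will overlap")
  }
  ill <- slm_illumination(geom, npad)
  A <- ill$amp
  ds <- geom$pitch / geom$demag
  xs <- centered_coords(npad, ds)
  XS <- matrix(xs, npad, npad)
  masks <- lapply(spots, function(s)          # rows = y, cols = x
    (XS - s$center_xyz[2])^2 + (t(XS) - s$center_xyz[1])^2 <=
      (s$diameter / 2)^2)
  req <- vapply(spots, `[[`, numeric(1), "weight")
  w <- req / mean(req)
  sup <- Reduce(`|`, masks)
  escale <- sqrt(sum(A^2) * length(A))
  phi <- with_seed(seed, matrix(stats::runif(npad^2, 0, 2 * pi), npad, npad))
  hist <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    Ff <- cfft2(A * exp(1i * phi))
    amp <- Mod(Ff)
    # per-spot achieved amplitude, normalised by the requested weights
    ach <- vapply(seq_along(masks),
                  function(k) mean(amp[masks[[k]]]) / sqrt(req[k]),
                  numeric(1))
    hist[it] <- stats::cor(as.vector(amp^2), as.vector(sup + 0))
    if (it > 1) w <- w * mean(ach) / ach
    targ <- matrix(0, npad, npad)
    for (k in seq_along(masks))
      targ[masks[[k]]] <- sqrt(req[k]) * w[k]
    targ <- targ * escale / sqrt(sum(targ^2))
    newamp <- ifelse(sup, targ, amp)
    back <- cifft2(newamp * exp(1i * Arg(Ff)))
    phi <- Arg(back)
  }
  mask <- phase_mask(phi[ill$rows, ill$cols], geom)
  attr(mask, "history") <- hist
  attr(mask, "npad") <- npad
  attr(mask, "spot_weights") <- w
  mask
}

#' Target amplitude for disk spots on the hologram sample grid
#'
#' @param spots A [spot_spec()] or list of them.
#' @param geom An [slm_geometry()].
#' @param npad Working grid size.
#' @return Centered `npad x npad` amplitude matrix (0/1 disks scaled by
#'   `sqrt(weight)`).
#' @export
disk_target <- function(spots, geom = slm_geometry(), npad = pad_size(geom)) {
  if (inherits(spots, "spot_spec")) spots <- list(spots)
  ds <- geom$pitch / geom$demag
  xs <- centered_coords(npad, ds)
  XS <- matrix(xs, npad, npad)
  targ <- matrix(0, npad, npad)
  for (s in spots) {
    m <- (XS - s$center_xyz[2])^2 + (t(XS) - s$center_xyz[1])^2 <=
      (s$diameter / 2)^2
    targ[m] <- sqrt(s$weight)
  }
  targ
}

#' Reconstruct the focal field of a hologram
#'
#' Fourier transform of the illuminated phase mask, returned at sample-plane
#' sampling (`pitch / demag` per pixel, centered).
#'
#' @param mask A [phase_mask()].
#' @return An [excitation_map()] carrying the complex focal field.
#' @export
reconstruct_hologram <- function(mask) {
  geom <- mask$geometry
  npad <- pad_size(geom)
  phi <- embed_phase(mask$phase, geom, npad)
  A <- slm_illumination(geom, npad)$amp
  field <- cfft2(A * exp(1i * phi)) / npad      # centered, unit-energy scale
  excitation_map(Mod(field)^2, geom$pitch / geom$demag, field = field)
}
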