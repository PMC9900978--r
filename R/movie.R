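#' Camera acquisition settings
#'
#' @param pixel_size Sample-plane pixel (um); 0.1625 for the reference
#'   detection path.
#' @param exposure Exposure per frame (ms).
#' @param readout Row-readout dead time (ms).
#' @param n_rows,n_cols Frame size (pixels).
#' @param offset Camera offset (counts).
#' @param read_noise Gaussian read noise s.d. (counts).
#' @param gain Counts per detected photon.
#' @param bit_depth Bit depth of the digitiser.
#' @return An object of class `acquisition_spec`; `frame_period` is
#'   `exposure + readout` (ms).
#' @export
acquisition_spec <- function(pixel_size = 0.1625, exposure = 1,
                             readout = 0.02, n_rows = 100L, n_cols = 100L,
                             offset = 100, read_noise = 1.5, gain = 1,
                             bit_depth = 16L) {
  stopifnot(exposure > 0, readout >= 0, n_rows > 0, n_cols > 0, gain > 0)
  structure(list(pixel_size = pixel_size, exposure = exposure,
                 readout = readout, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), offset = offset,
                 read_noise = read_noise, gain = gain,
                 bit_depth = as.integer(bit_depth),
                 frame_period = exposure + readout),
            class = "acquisition_spec")
}

#' Membrane-annulus cell specification
#'
#' A soma is modelled as an annulus of membrane pixels (the equatorial
#' optical section of a ~12 um sphere) with optional per-pixel responsivity
#' heterogeneity multiplying the sensor sensitivity.
#'
#' @param centroid_xy Cell center in the frame (um, frame-centered origin).
#' @param radius Soma radius (um).
#' @param membrane_thickness Annulus thickness (um).
#' @param expression Mean photon rate per membrane pixel at baseline
#'   (photons/pixel/ms) at the rendering reference power.
#' @param responsivity_sd Log-normal s.d. of per-pixel responsivity
#'   multipliers (0 = homogeneous).
#' @param seed Seed for the heterogeneity draw (deterministic per cell).
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(centroid_xy = c(0, 0), radius = 6,
                      membrane_thickness = 1, expression = 30,
                      responsivity_sd = 0, seed = 1L) {
  stopifnot(radius > 0, membrane_thickness > 0, expression >= 0,
            responsivity_sd >= 0)
  structure(list(centroid_xy = centroid_xy, radius = radius,
                 membrane_thickness = membrane_thickness,
                 expression = expression, responsivity_sd = responsivity_sd,
                 seed = as.integer(seed)),
            class = "cell_spec")
}

# membrane pixel indices and per-pixel responsivity for a cell on the camera
# grid; returns list(idx, resp, r (radius per pixel um))
membrane_pixels <- function(cell, acq) {
  ys <- centered_coords(acq$n_rows, acq$pixel_size) - cell$centroid_xy[2]
  xs <- centered_coords(acq$n_cols, acq$pixel_size) - cell$centroid_xy[1]
  R <- sqrt(outer(ys^2, xs^2, `+`))
  idx <- which(abs(R - cell$radius) <= cell$membrane_thickness / 2)
  resp <- rep(1, length(idx))
  if (cell$responsivity_sd > 0)
    resp <- with_seed(cell$seed,
      stats::rlnorm(length(idx), -cell$responsivity_sd^2 / 2,
                    cell$responsivity_sd))
  list(idx = idx, resp = resp, r = R[idx])
}

#' Render a synthetic voltage-imaging camera movie
#'
#' Forward model: per frame, the expected photon count of each membrane
#' pixel is `expression * (P/Pref)^2 * exc2 * (1 + resp * dFF) * bleach *
#' exposure` while the illumination gate is open; a Poisson draw, the camera
#' offset and Gaussian read noise yield the recorded counts. Bleaching
#' advances only with illuminated time and partially recovers across dark
#' intervals (see [sensor_model()]). Background fluorescence is added inside
#' the excitation spot.
#'
#' @param cells A [cell_spec()] or list of them.
#' @param protocol A [make_protocol()] result.
#' @param acq An [acquisition_spec()].
#' @param sensor A [sensor_model()].
#' @param seed Integer seed; identical seeds give bit-identical movies.
#' @param excitation `NULL` for an ideal flat-top spot matching each cell's
#'   diameter, or a 2D [excitation_map()] centred on each cell.
#' @param power_density Excitation power density (mW/um^2).
#' @param reference_density Power density at which `expression` is quoted.
#' @param background_rate Background photons/pixel/ms inside the spot.
#' @param voltages Optional list of per-cell voltage commands (defaults to
#'   the protocol command for every cell).
#' @param events Optional list of per-cell event times recorded in the truth.
#' @return List with `movie` (class `vi_movie`: integer array
#'   `[rows, cols, frames]`, `acq`, `meta`) and `truth` (class
#'   `ground_truth`: per-frame times, per-cell voltage and noiseless dF/F,
#'   bleach factors, illumination state, event times).
#' @export
render_movie <- function(cells, protocol, acq = acquisition_spec(),
                         sensor = sensor_model(), seed = 1L,
                         excitation = NULL, power_density = 1.33,
                         reference_density = 1.33, background_rate = 0.5,
                         voltages = NULL, events = NULL) {
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  n_cells <- length(cells)
  tt <- protocol$time; dt <- protocol$dt
  duration <- tt[length(tt)] + dt / 2
  fp <- acq$frame_period
  n_frames <- floor(duration / fp)
  if (n_frames < 1) stop("protocol shorter than one frame period")
  frame_start <- (seq_len(n_frames) - 1) * fp
  # supersample windows via cumulative sums (tt is a uniform grid)
  i0 <- pmin(ceiling(frame_start / dt + 0.5 - 1e-9) - 1, length(tt))
  i1 <- pmin(ceiling((frame_start + acq$exposure) / dt + 0.5 - 1e-9) - 1,
             length(tt))
  nw <- pmax(i1 - i0, 1L)
  win_mean <- function(x) {
    cs <- c(0, cumsum(x))
    (cs[i1 + 1] - cs[i0 + 1]) / nw
  }
  lit_ms <- win_mean(protocol$gate) * nw * dt
  lit_frac <- lit_ms / acq$exposure
  bleach <- bleach_factors(lit_ms, sensor, power_density)
  pscale <- (power_density / reference_density)^2
  # per-cell geometry, excitation and dff
  mem <- lapply(cells, membrane_pixels, acq = acq)
  exc2 <- vector("list", n_cells)
  spot <- matrix(0, acq$n_rows, acq$n_cols)   # spot support for background
  for (i in seq_len(n_cells)) {
    cl <- cells[[i]]
    if (is.null(excitation)) {
      exc2[[i]] <- rep(1, length(mem[[i]]$idx))
      ys <- centered_coords(acq$n_rows, acq$pixel_size) - cl$centroid_xy[2]
      xs <- centered_coords(acq$n_cols, acq$pixel_size) - cl$centroid_xy[1]
      spot[outer(ys^2, xs^2, `+`) <= (cl$radius + 1)^2] <- 1
    } else {
      rs <- if (abs(excitation$pixel_size - acq$pixel_size) > 1e-9)
        resample_map(excitation, acq$pixel_size) else excitation
      tp <- rs$two_photon
      ridx <- arrayInd(mem[[i]]$idx, c(acq$n_rows, acq$n_cols))
      py <- centered_coords(acq$n_rows, acq$pixel_size)[ridx[, 1]] -
        cl$centroid_xy[2]
      px <- centered_coords(acq$n_cols, acq$pixel_size)[ridx[, 2]] -
        cl$centroid_xy[1]
      iy <- pmin(pmax(round(py / rs$pixel_size) + nrow(tp) / 2 + 1, 1),
                 nrow(tp))
      ix <- pmin(pmax(round(px / rs$pixel_size) + ncol(tp) / 2 + 1, 1),
                 ncol(tp))
      exc2[[i]] <- tp[cbind(iy, ix)]
      ys <- centered_coords(acq$n_rows, acq$pixel_size) - cl$centroid_xy[2]
      xs <- centered_coords(acq$n_cols, acq$pixel_size) - cl$centroid_xy[1]
      spot[outer(ys^2, xs^2, `+`) <= (cl$radius + 1)^2] <- 1
    }
  }
  dff_frames <- matrix(0, n_frames, n_cells)
  v_frames <- matrix(0, n_frames, n_cells)
  dff_ss <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    v <- if (is.null(voltages)) protocol$command else voltages[[i]]
    dff_ss[[i]] <- voltage_to_dff(v, dt, sensor, protocol$v_rest)
    dff_frames[, i] <- win_mean(dff_ss[[i]])
    v_frames[, i] <- win_mean(v)
  }
  npx <- acq$n_rows * acq$n_cols
  maxval <- 2^acq$bit_depth - 1
  bg_idx <- which(spot > 0)
  # per-frame photon dose shared by background and membrane
  dose <- bleach * lit_ms * pscale
  counts <- with_seed(seed, {
    base <- acq$offset +
      stats::rnorm(npx * n_frames, 0, acq$read_noise)   # offset + read noise
    dim(base) <- c(npx, n_frames)
    lit <- which(dose > 0)
    if (length(bg_idx) && length(lit)) {
      lam_bg <- outer(rep(background_rate, length(bg_idx)), dose[lit])
      base[bg_idx, lit] <- base[bg_idx, lit] +
        acq$gain * stats::rpois(length(lam_bg), lam_bg)
    }
    for (i in seq_len(n_cells)) {
      m <- mem[[i]]
      if (!length(m$idx) || !length(lit)) next
      resp_fac <- pmax(1 + outer(m$resp, dff_frames[lit, i]), 0)
      lam <- (cells[[i]]$expression * exc2[[i]]) * resp_fac *
        rep(dose[lit], each = length(m$idx))
      base[m$idx, lit] <- base[m$idx, lit] +
        acq$gain * stats::rpois(length(lam), lam)
    }
    round(base)
  })
  clipped <- any(counts > maxval)
  data <- array(as.integer(pmin(pmax(counts, 0), maxval)),
                c(acq$n_rows, acq$n_cols, n_frames))
  if (clipped)
    warning(sprintf("photon expectation exceeded the %d-bit range; clipped",
                    acq$bit_depth))
  movie <- structure(
    list(data = data, acq = acq,
         meta = list(kind = protocol$kind, seed = seed,
                     power_density = power_density,
                     acquisition_rate = protocol$acquisition_rate,
                     frame_period = fp, n_frames = n_frames)),
    class = "vi_movie")
  truth <- structure(
    list(frame_time = frame_start, voltage = v_frames, dff = dff_frames,
         bleach = bleach, lit = lit_frac >= 0.999, lit_frac = lit_frac,
         events = if (is.null(events)) rep(list(protocol$events), n_cells)
                  else events,
         epochs = protocol$epochs, cells = cells),
    class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' @export
print.vi_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vi_movie> %d x %d px, %d frames @ %.4g Hz\n",
              d[1], d[2], d[3], 1000 / x$meta$frame_period))
  invisible(x)
}

#' Optogenetic actuation model
#'
#' Per-pulse spiking outcome of a soma-targeted channelrhodopsin: the AP
#' probability rises with power density up to saturation, APs occur at a
#' fixed mean latency with Gaussian jitter, and rapid stimulation
#' desensitises the response (per-pulse probability decrement growing as the
#' inter-pulse interval shrinks).
#'
#' @param saturation_density Power density (mW/um^2) at which the
#'   photocurrent saturates.
#' @param prob_max Per-pulse AP probability at saturation for a rested cell.
#' @param hill Exponent of the sub-saturation probability rise.
#' @param latency_mean Mean AP latency after pulse onset (ms).
#' @param latency_jitter_sd Latency jitter s.d. (ms).
#' @param desens Maximal per-pulse desensitisation decrement.
#' @param desens_isi50 Inter-pulse interval (ms) below which desensitisation
#'   builds up.
#' @return An object of class `actuator_model`.
#' @export
actuator_model <- function(saturation_density = 0.02, prob_max = 0.85,
                           hill = 2, latency_mean = 4.3,
                           latency_jitter_sd = 1.0, desens = 0.15,
                           desens_isi50 = 100) {
  stopifnot(saturation_density > 0, prob_max >= 0, prob_max <= 1,
            latency_jitter_sd >= 0)
  structure(as.list(environment()), class = "actuator_model")
}

#' Simulate photostimulation-evoked action potentials
#'
#' @param actuator An [actuator_model()].
#' @param stim Data frame with `onset` (ms) and `power_density`; a
#'   `duration` column is carried through but does not affect the outcome.
#' @param seed Integer seed.
#' @param n_cells Number of independent cells.
#' @return List per cell: `events` (AP times, ms) and `pulses` (data frame:
#'   onset, power, probability applied, spiked, latency).
#' @export
simulate_actuation <- function(actuator, stim, seed = 1L, n_cells = 1L) {
  stopifnot(is.data.frame(stim), nrow(stim) >= 1)
  p_base <- actuator$prob_max *
    pmin(1, stim$power_density / actuator$saturation_density)^actuator$hill
  isi <- c(Inf, diff(stim$onset))
  with_seed(seed, {
    lapply(seq_len(n_cells), function(ic) {
      state <- 1
      prob <- numeric(nrow(stim))
      for (j in seq_len(nrow(stim))) {
        if (is.finite(isi[j]))
          state <- state *
            (1 - actuator$desens * max(0, 1 - isi[j] / actuator$desens_isi50))
        prob[j] <- p_base[j] * state
      }
      spiked <- stats::runif(nrow(stim)) < prob
      lat <- actuator$latency_mean +
        stats::rnorm(nrow(stim), 0, actuator$latency_jitter_sd)
      lat <- pmax(lat, 0.5)
      events <- stim$onset[spiked] + lat[spiked]
      list(events = events,
           pulses = data.frame(onset = stim$onset,
                               power_density = stim$power_density,
                               probability = prob, spiked = spiked,
                               latency = ifelse(spiked, lat, NA_real_)))
    })
  })
}
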