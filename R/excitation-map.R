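#' Excitation map container
#'
#' Holds a 2D focal-plane (or 3D volumetric) excitation intensity pattern at
#' sample-plane sampling, together with its elementwise-squared (two-photon)
#' counterpart. The two-photon array is normalised to peak 1.
#'
#' @param intensity Nonnegative 2D matrix or 3D array (x, y[, z]).
#' @param pixel_size Lateral sample-plane pixel (um).
#' @param z_step Axial step (um) for 3D stacks, `NA` for single planes.
#' @param z Axial coordinates (um) for 3D stacks.
#' @param field Optional complex focal field (2D) from which `intensity` was
#'   derived; kept for propagation.
#' @return An object of class `excitation_map`.
#' @export
excitation_map <- function(intensity, pixel_size, z_step = NA_real_,
                           z = NULL, field = NULL) {
  stopifnot(all(intensity >= 0), pixel_size > 0)
  tp <- intensity^2
  mx <- max(tp)
  if (mx > 0) tp <- tp / mx
  structure(list(intensity = intensity, two_photon = tp,
                 pixel_size = pixel_size, z_step = z_step, z = z,
                 field = field),
            class = "excitation_map")
}

#' @export
print.excitation_map <- function(x, ...) {
  d <- dim(x$intensity)
  cat("<excitation_map> ", paste(d, collapse = " x "),
      sprintf(" @ %.4g um/px", x$pixel_size),
      if (!is.na(x$z_step)) sprintf(", z step %.3g um", x$z_step), "\n",
      sep = "")
  invisible(x)
}

#' Lateral coordinates of an excitation map
#'
#' @param map An `excitation_map`.
#' @return Vector of centered lateral coordinates (um).
#' @export
map_coords <- function(map) centered_coords(nrow(map$intensity), map$pixel_size)

#' Resample a 2D excitation map onto a different pixel size
#'
#' Bilinear interpolation onto a centered grid, used to bring optical
#' simulations (SLM-conjugate sampling) onto the camera grid.
#'
#' @param map A 2D `excitation_map`.
#' @param pixel_size Target pixel (um).
#' @param n Output grid side length (pixels); defaults to covering the input.
#' @return A new `excitation_map`.
#' @export
resample_map <- function(map, pixel_size, n = NULL) {
  stopifnot(length(dim(map$intensity)) == 2)
  if (is.null(n))
    n <- floor(nrow(map$intensity) * map$pixel_size / pixel_size / 2) * 2
  src_x <- map_coords(map)
  out_x <- centered_coords(n, pixel_size)
  I <- map$intensity
  # interpolate rows then columns
  tmp <- apply(I, 2, function(col)
    stats::approx(src_x, col, xout = out_x, rule = 2, ties = "ordered")$y)
  out <- t(apply(tmp, 1, function(row)
    stats::approx(src_x, row, xout = out_x, rule = 2, ties = "ordered")$y))
  excitation_map(pmax(out, 0), pixel_size)
}
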