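# FFT-grid helpers shared by the light-sculpting code. Arrays are row-major
# (rows = y, cols = x); centered arrays put the optical axis on the sample at
# index n/2+1 so that fields and spectra share one origin.

fft_freqs <- function(n, d) c(seq(0, n / 2 - 1), seq(-n / 2, -1)) / (n * d)

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}

ifftshift2 <- fftshift2  # even sizes only, used internally

# Centered 2D transforms: arrays have their origin at index (n/2+1, n/2+1),
# so fields and spectra can be composed (propagated, filtered) without
# carrying DFT phase ramps.
cfft2 <- function(f) fftshift2(stats::fft(ifftshift2(f)))
cifft2 <- function(F) fftshift2(stats::fft(ifftshift2(F), inverse = TRUE)) /
  length(F)

# centered frequency coordinates matching cfft2 output (zero at n/2+1)
centered_freqs <- function(n, d) (seq_len(n) - n / 2 - 1) / (n * d)

# centered coordinate vector for n samples of size d; the origin lies on the
# sample at index n/2+1, matching the centered-FFT convention
centered_coords <- function(n, d) (seq_len(n) - n / 2 - 1) * d

# next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(n))

# padded square working grid for an SLM geometry
pad_size <- function(geom) next_pow2(max(geom$n_rows, geom$n_cols))

# Gaussian illumination amplitude clipped to the SLM panel, embedded in the
# padded grid. Returns list(amp, rows, cols) with the embedding indices.
slm_illumination <- function(geom, npad = pad_size(geom)) {
  x <- centered_coords(npad, geom$pitch)
  X <- matrix(x, npad, npad)
  amp <- exp(-(X^2 + t(X)^2) / geom$beam_waist^2)
  rows <- (npad - geom$n_rows) %/% 2 + seq_len(geom$n_rows)
  cols <- (npad - geom$n_cols) %/% 2 + seq_len(geom$n_cols)
  panel <- matrix(0, npad, npad)
  panel[rows, cols] <- 1
  list(amp = amp * panel, rows = rows, cols = cols)
}

# embed an SLM-sized phase matrix into the padded grid (phase 0 outside)
embed_phase <- function(phase, geom, npad = pad_size(geom)) {
  rows <- (npad - geom$n_rows) %/% 2 + seq_len(geom$n_rows)
  cols <- (npad - geom$n_cols) %/% 2 + seq_len(geom$n_cols)
  full <- matrix(0, npad, npad)
  full[rows, cols] <- phase
  full
}

crop_center <- function(m, size) {
  n <- nrow(m)
  idx <- (n - size) %/% 2 + seq_len(size)
  m[idx, idx, drop = FALSE]
}

# linear interpolation FWHM of a 1-d profile; errors if the profile does not
# drop below half maximum on both sides of the peak
fwhm_1d <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  hm <- max(y) / 2
  above <- which(y >= hm)
  lo <- min(above); hi <- max(above)
  if (lo == 1 || hi == length(y))
    stop("profile does not drop below half-maximum within the grid")
  lerp <- function(x1, x2, y1, y2) x1 + (hm - y1) * (x2 - x1) / (y2 - y1)
  xl <- lerp(x[lo - 1], x[lo], y[lo - 1], y[lo])
  xr <- lerp(x[hi], x[hi + 1], y[hi], y[hi + 1])
  xr - xl
}

# run a block with a deterministic, restored RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  force(code)
}
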