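make_trace <- function(raw, fp = 1, lit = NULL, epochs = NULL, dff = NULL) {
  n <- length(raw)
  structure(list(time = (seq_len(n) - 1) * fp, raw_f = raw,
                 lit = lit %||% rep(TRUE, n),
                 epochs = epochs %||% data.frame(start = 0, end = n * fp),
                 frame_period = fp, baseline = NULL, f0 = raw[1],
                 dff = dff),
            class = "vi_trace")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("shot-noise SNR is the exact amplitude-photon identity", {
  n <- 200
  dff <- c(rep(0, 100), rep(-0.5, 50), rep(0, 50))
  dff[1:100] <- dff[1:100] + rnorm(100, 0, 1e-6)
  tr <- make_trace(rep(400, n), dff = dff)
  m <- snr_metrics(tr, response_window = c(100, 150),
                   baseline_window = c(0, 100))
  expect_equal(m$snr_shot, 0.5 * sqrt(400), tolerance = 1e-3)
  # doubling illumination (two-photon: F0 x4) doubles snr_shot
  tr2 <- make_trace(rep(1600, n), dff = dff)
  m2 <- snr_metrics(tr2, response_window = c(100, 150),
                    baseline_window = c(0, 100))
  expect_equal(m2$snr_shot / m$snr_shot, 2, tolerance = 1e-3)
  expect_error(snr_metrics(tr, c(50, 150), c(0, 100)), "overlap")
})

test_that("pure-Poisson steps are shot-noise limited", {
  set.seed(3)
  f0 <- 2000
  lam <- c(rep(f0, 600), rep(f0 * 0.6, 200), rep(f0, 200))
  raw <- rpois(1000, lam)
  base <- c(rep(TRUE, 600), rep(FALSE, 200), rep(TRUE, 200))
  bl <- rep(mean(raw[base]), 1000)
  tr <- make_trace(raw, dff = raw / bl - 1)
  m <- snr_metrics(tr, response_window = c(600, 800),
                   baseline_window = c(0, 600))
  expect_equal(m$snr_empirical / m$snr_shot, 1, tolerance = 0.1)
})

test_that("photostability integrates the normalised baseline trace", {
  expect_equal(photostability(make_trace(rep(500, 100))), 1)
  # linear decay to 0.6 F0 -> trapezoidal mean 0.8
  n <- 1000
  tr <- make_trace(seq(1000, 600, length.out = n))
  expect_equal(photostability(tr), 0.8, tolerance = 0.001)
  # invariant under rescaling
  tr2 <- make_trace(3 * seq(1000, 600, length.out = n))
  expect_equal(photostability(tr2), photostability(tr))
  expect_error(photostability(make_trace(c(-1, rep(1, 10)))), "positive")
})

test_that("photorecovery reports per-epoch ratios", {
  fp <- 10
  epochs <- data.frame(start = c(0, 1000, 2000), end = c(200, 1200, 2200))
  lit <- rep(FALSE, 300)
  for (k in 1:3) lit[(epochs$start[k] / fp + 1):(epochs$end[k] / fp)] <- TRUE
  raw <- rep(0, 300)
  raw[lit] <- rep(c(1000, 970, 970), each = 20)
  tr <- make_trace(raw, fp = fp, lit = lit, epochs = epochs)
  pr <- photorecovery(tr, prestep_ms = 200)
  expect_equal(pr$ratios, c(1, 0.97, 0.97))
  expect_equal(pr$mean_recovery, 0.97)
  # single epoch errors
  tr1 <- make_trace(rep(1, 100), epochs = data.frame(start = 0, end = 100))
  expect_error(photorecovery(tr1), "two illumination epochs")
})

test_that("photorecovery of the generator matches its recovery fraction", {
  # equilibrating, fully recoverable bleach at recovery 0.97
  sens <- sensor_model(bleach_fast_frac = 1, bleach_fast_tau = 0.05,
                       recovery_fraction = 0.97)
  pr <- make_protocol("protocol2")
  tr <- render_trace(pr, 2e5, sensor = sens, seed = 4,
                     exposure = 9.98, read_sd = 0)
  rec <- photorecovery(tr)
  expect_equal(rec$mean_recovery, 0.97, tolerance = 0.01)
  # without recovery the ratios decrease strictly
  sens0 <- sensor_model(bleach_fast_frac = 1, bleach_fast_tau = 0.5,
                        recovery_fraction = 0)
  tr0 <- render_trace(pr, 2e5, sensor = sens0, seed = 4,
                      exposure = 9.98, read_sd = 0)
  r0 <- photorecovery(tr0)$ratios
  expect_true(all(diff(r0) < 0))
})

test_that("power-response fits recover the two-photon exponent", {
  p <- c(0.66, 0.88, 1.11, 1.33, 1.55)
  set.seed(5)
  # shot-noise-limited synthetic series: F0 ~ P^2, SNR ~ P
  ser <- data.frame(power_density = p, f0 = 3000 * (p / 0.66)^2,
                    snr = 400 * p / 0.66, dff = 43 - p)
  fit <- fit_power_response(ser)
  expect_equal(fit$f0_power_exponent, 2, tolerance = 1e-6)
  expect_gte(fit$snr_power_r2, 0.999)
  expect_equal(fit$dff_trend, -1)
  # linear (one-photon) control
  ser1 <- transform(ser, f0 = 3000 * p / 0.66)
  expect_equal(fit_power_response(ser1)$f0_power_exponent, 1,
               tolerance = 1e-6)
  # exponent recovery across noisy seeded series
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    f0 <- 3000 * (p / 0.66)^2 * exp(rnorm(5, 0, 0.01))
    fit_power_response(data.frame(power_density = p, f0 = f0,
                                  snr = 400 * p))$f0_power_exponent - 2
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
  expect_error(fit_power_response(data.frame(power_density = p,
                                             f0 = c(-1, 1, 1, 1, 1),
                                             snr = p)), "positive")
})

test_that("resolution curves recover spot-convolved widths", {
  # delta-like response: FWHM equals the scan step
  expect_equal(resolution_curve(seq(-10, 10, 2), c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)), 2)
  # lateral displacement scan of the synthesized 12 um GPC spot over a
  # granule-cell soma (10 um) with a mild scattering blur (sigma 2 um,
  # the slice-imaging depth regime)
  em <- gpc_synthesize(make_gpc_mask(spot_spec(diameter = 12),
                                     slm_geometry()))
  tp <- crop_center_test(em$two_photon, 192)
  ps <- em$pixel_size
  n <- nrow(tp)
  fx <- c(seq(0, n / 2 - 1), seq(-n / 2, -1)) / (n * ps)
  FX <- matrix(fx, n, n)
  H <- exp(-2 * pi^2 * 2^2 * (FX^2 + t(FX)^2))
  tpb <- Re(stats::fft(stats::fft(tp) * H, inverse = TRUE)) / n^2
  xs <- (seq_len(n) - n / 2 - 1) * ps
  X <- matrix(xs, n, n)
  disp <- seq(-20, 20, by = 1)
  resp <- vapply(disp, function(d) {
    shifted <- sqrt((X - d)^2 + t(X)^2)
    sum(tpb[abs(shifted - 5) <= 0.5])
  }, numeric(1))
  fw <- resolution_curve(disp, resp)
  expect_between(fw, 12, 16)
  # symmetric input: symmetric half-max crossings
  expect_equal(resp, rev(resp), tolerance = 1e-3)
  expect_error(resolution_curve(c(0, 1, 2), c(1, 0.9, 0.8)))
})
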