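test_that("rendered movies obey the photon bookkeeping", {
  sim <- quick_movie(expression = 0, seed = 4)
  # zero expression: offset plus read noise only
  expect_equal(mean(sim$movie$data), sim$acq$offset, tolerance = 0.5)
  # frame count
  dur <- max(sim$protocol$time) + sim$protocol$dt / 2
  expect_equal(dim(sim$movie$data)[3], floor(dur / sim$acq$frame_period))
  # determinism: identical seed, bit-identical movie
  s1 <- quick_movie(seed = 9)
  s2 <- quick_movie(seed = 9)
  expect_identical(s1$movie$data, s2$movie$data)
  expect_false(identical(s1$movie$data, quick_movie(seed = 10)$movie$data))
})

test_that("two-photon square law: doubling power quadruples photon rates", {
  pr <- make_protocol("protocol3")
  acq <- acquisition_spec(pixel_size = 0.325, exposure = 0.98,
                          n_rows = 50L, n_cols = 50L)
  cell <- cell_spec(expression = 50, seed = 3)
  m1 <- render_movie(cell, pr, acq, seed = 1, power_density = 0.5,
                     reference_density = 0.5)$movie
  m2 <- render_movie(cell, pr, acq, seed = 1, power_density = 1.0,
                     reference_density = 0.5)$movie
  # baseline membrane counts, offset-subtracted, frames before the train
  f1 <- mean(m1$data[, , 15:25]) - acq$offset
  f2 <- mean(m2$data[, , 15:25]) - acq$offset
  expect_equal(f2 / f1, 4, tolerance = 0.05)
})

test_that("photon statistics are Poisson on constant-voltage segments", {
  pr <- make_protocol("protocol1", params = list(acquisition_rate = 100))
  acq <- acquisition_spec(pixel_size = 0.325, exposure = 9.98,
                          n_rows = 50L, n_cols = 50L, read_noise = 0)
  sim <- render_movie(cell_spec(expression = 5, seed = 2), pr, acq,
                      seed = 11, background_rate = 0)
  mem <- voltim:::membrane_pixels(cell_spec(expression = 5, seed = 2), acq)
  flat <- array(sim$movie$data, c(2500, dim(sim$movie$data)[3]))
  seg <- flat[mem$idx, 5:45] - acq$offset   # pre-step constant segment
  # variance ~ mean per pixel after offset subtraction
  ratio <- mean(apply(seg, 1, var)) / mean(seg)
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("ground-truth dF/F matches the rendered membrane fluorescence", {
  sim <- quick_movie(expression = 500, seed = 6,
                     sensor = sensor_model(bleach_fast_tau = 1e6,
                                           bleach_slow_tau = 1e6))
  mem <- voltim:::membrane_pixels(sim$cell, sim$acq)
  flat <- array(sim$movie$data, c(2500, dim(sim$movie$data)[3]))
  tr <- colMeans(flat[mem$idx, ]) - sim$acq$offset
  lit <- sim$truth$lit
  # regress measured dff on truth dff over lit frames
  base <- median(tr[lit][1:20])
  meas <- tr[lit] / base - 1
  tru <- sim$truth$dff[lit, 1]
  slope <- coef(lm(meas ~ tru))[2]
  expect_equal(unname(slope), 1, tolerance = 0.01)
})

test_that("actuation model reproduces its configured statistics", {
  act <- actuator_model()
  # saturated, slow stimulation of a rested cell: probability >= 0.75
  stim <- data.frame(onset = seq(0, by = 200, length.out = 2000),
                     power_density = 0.03)
  res <- simulate_actuation(act, stim, seed = 3)[[1]]
  expect_gte(mean(res$pulses$spiked), 0.75)
  # no power, no events
  stim0 <- transform(stim, power_density = 0)
  expect_length(simulate_actuation(act, stim0, seed = 3)[[1]]$events, 0)
  # latency recovery over 10^4 pulses
  stim4 <- data.frame(onset = seq(0, by = 200, length.out = 1e4),
                      power_density = 0.05)
  r4 <- simulate_actuation(act, stim4, seed = 5)[[1]]
  lat <- r4$pulses$latency[r4$pulses$spiked]
  expect_equal(mean(lat), 4.3, tolerance = 0.1)
  # desensitisation: high-frequency trains evoke fewer spikes per pulse
  fast <- data.frame(onset = seq(0, by = 20, length.out = 2000),
                     power_density = 0.03)
  rf <- simulate_actuation(act, fast, seed = 3)[[1]]
  expect_lt(mean(rf$pulses$spiked), mean(res$pulses$spiked))
})

test_that("a supplied excitation map attenuates membrane photon rates", {
  pr <- make_protocol("protocol3")
  acq <- acquisition_spec(pixel_size = 0.325, exposure = 0.98,
                          n_rows = 50L, n_cols = 50L)
  cell <- cell_spec(expression = 100, seed = 3)
  # soft-edged spot: two-photon excitation < 1 over much of the annulus
  exc <- gaussian_flattop_spot(12, uniformity = 0.4)$map
  m_flat <- render_movie(cell, pr, acq, seed = 2)$movie
  m_soft <- render_movie(cell, pr, acq, seed = 2, excitation = exc)$movie
  f <- function(m) mean(m$data[, , 15:25]) - acq$offset
  expect_lt(f(m_soft), 0.7 * f(m_flat))
  expect_gt(f(m_soft), 0.05 * f(m_flat))
})
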