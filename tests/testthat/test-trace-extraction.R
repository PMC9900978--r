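test_that("initial segmentation finds the membrane annulus", {
  sim <- quick_movie(seed = 3, expression = 50)
  mask <- initial_segmentation(sim$movie)
  mem <- voltim:::membrane_pixels(sim$cell, sim$acq)
  truth <- rep(FALSE, 2500)
  truth[mem$idx] <- TRUE
  jac <- sum(mask & matrix(truth, 50, 50)) / sum(mask | matrix(truth, 50, 50))
  expect_gte(jac, 0.5)
  # blank movie errors
  blank <- quick_movie(seed = 4, expression = 0)
  expect_error(initial_segmentation(blank$movie), "no cell")
})

test_that("regression weighting doubles weights of doubly responsive pixels", {
  # two-population cell: half the membrane responds twice as strongly
  pr <- make_protocol("protocol1", params = list(acquisition_rate = 100))
  acq <- acquisition_spec(pixel_size = 0.325, exposure = 9.98,
                          n_rows = 50L, n_cols = 50L)
  cell <- cell_spec(expression = 300, seed = 5)
  mem <- voltim:::membrane_pixels(cell, acq)
  sim <- render_movie(cell, pr, acq, seed = 7)
  # rebuild the movie with a two-population responsivity by mixing two
  # renders is costly; instead check the slope contract directly on pixels
  mask <- initial_segmentation(sim$movie)
  wm <- regression_weight_mask(sim$movie, mask)
  # homogeneous cell: positive weights cluster around their mean
  win <- wm$weights[wm$support]
  expect_lt(stats::sd(win) / mean(win), 0.5)
  expect_equal(wm$n_pixels_initial / wm$n_pixels_final, 2, tolerance = 0.5)
  # no-structure error
  flat <- array(100L, c(10, 10, 120))
  m <- matrix(TRUE, 10, 10)
  expect_error(regression_weight_mask(flat, m), "temporal structure")
})

test_that("doubled responsivity yields doubled regression weight", {
  # explicit two-population synthetic ROI built from the linear model
  set.seed(11)
  n_frames <- 300
  common <- sin(seq(0, 6 * pi, length.out = n_frames)) * 10
  px <- matrix(0, 64, n_frames)
  resp <- rep(c(1, 2), each = 32)
  for (i in 1:64) px[i, ] <- 500 + resp[i] * common + rnorm(n_frames, 0, 2)
  movie <- array(as.integer(round(px)), c(8, 8, n_frames))
  mask <- matrix(TRUE, 8, 8)
  wm <- regression_weight_mask(movie, mask, support_quantile = 0)
  w <- wm$weights
  ratio <- mean(w[33:64]) / mean(w[1:32])
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("trace extraction is a normalised weighted mean", {
  sim <- quick_movie(seed = 3, expression = 200,
                     sensor = sensor_model(bleach_fast_tau = 1e6,
                                           bleach_slow_tau = 1e6))
  d <- dim(sim$movie$data)
  w <- matrix(0, d[1], d[2]); w[25, 25] <- 3
  tr <- extract_trace(sim$movie, w)
  expect_equal(tr$raw_f,
               as.numeric(sim$movie$data[25, 25, ]) - sim$acq$offset)
  # scale invariance
  tr2 <- extract_trace(sim$movie, w * 7)
  expect_identical(tr$raw_f, tr2$raw_f)
  # uniform weights over the true membrane recover the ground-truth trace
  mem <- voltim:::membrane_pixels(sim$cell, sim$acq)
  wt <- matrix(0, d[1], d[2]); wt[mem$idx] <- 1
  tru <- extract_trace(sim$movie, wt, sim$truth)
  tru <- detrend_dff(tru)
  lit <- sim$truth$lit
  expect_gte(stats::cor(tru$dff[lit], sim$truth$dff[lit, 1]), 0.99)
})

test_that("detrending recovers dF/F without touching the raw trace", {
  sim <- quick_movie(seed = 5, expression = 200,
                     sensor = sensor_model(bleach_fast_tau = 1e6,
                                           bleach_slow_tau = 1e6))
  tr <- extract_trace(sim$movie, initial_segmentation(sim$movie), sim$truth)
  raw_before <- tr$raw_f
  tr <- detrend_dff(tr)
  expect_identical(tr$raw_f, raw_before)      # immutability
  lit <- sim$truth$lit
  # bleach-free: baseline ~ constant, dff matches truth within 0.01
  expect_lt(stats::sd(tr$baseline[lit]) / mean(tr$baseline[lit]), 0.01)
  expect_lt(max(abs(tr$dff[lit] - sim$truth$dff[lit, 1])), 0.01 + 0.43 * 0.05)
  # pure double-exponential decay, no events -> dff ~ 0
  n <- 400
  t0 <- seq_len(n)
  raw <- 1000 * (0.3 * exp(-t0 / 80) + 0.7 * exp(-t0 / 2000))
  set.seed(2)
  raw <- raw + rnorm(n, 0, 1)
  tr2 <- structure(list(time = (t0 - 1) * 10, raw_f = raw,
                        lit = rep(TRUE, n),
                        epochs = data.frame(start = 0, end = n * 10),
                        frame_period = 10, baseline = NULL, dff = NULL,
                        f0 = NULL),
                   class = "vi_trace")
  tr2 <- detrend_dff(tr2)
  expect_lt(max(abs(tr2$dff)), 0.02)
})

test_that("extracted step amplitudes are unbiased across response sizes", {
  # cells with true step responses between -10 and -50 %dF/F0
  amps_true <- seq(10, 50, length.out = 8)
  err <- vapply(seq_along(amps_true), function(i) {
    sens <- sensor_model(sensitivity = -amps_true[i] / 100,
                         bleach_fast_tau = 50, bleach_slow_tau = 500)
    sim <- quick_movie(seed = 100 + i, expression = 300, sensor = sens)
    tr <- detrend_dff(extract_trace(sim$movie,
                                    initial_segmentation(sim$movie),
                                    sim$truth))
    m <- voltim:::step_response_metrics(tr, sim$protocol$events)
    100 * m$amp - amps_true[i]
  }, numeric(1))
  expect_lt(abs(mean(err)), 2)
  expect_lt(sqrt(mean(err^2)), 4)
})
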