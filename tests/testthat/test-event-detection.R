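# synthetic spike trace at a given per-event SNR (photon-level model)
spike_trace <- function(n_ap = 50, isi_ms = 1000, rate = 1000, snr = 14,
                        seed = 1, amp = 0.30) {
  pr <- make_protocol("ap_train",
                      params = list(rate_hz = 1000 / isi_ms, n_ap = n_ap,
                                    acquisition_rate = rate, tail_ms = 200))
  f0 <- (snr / amp)^2            # shot-noise budget: snr = amp sqrt(F0)
  exposure <- 1000 / rate - 0.02
  tr <- render_trace(pr, f0 * exposure / 0.98, seed = seed,
                     exposure = exposure, read_sd = 0)
  list(trace = detrend_dff(tr), events = pr$events)
}

test_that("template matching detects all spikes at high SNR with no false positives", {
  st <- spike_trace(n_ap = 50, isi_ms = 1000, snr = 14, seed = 2)
  sp <- detect_spikes(st$trace)
  sc <- score_detection(sp, st$events, tolerance = 5)
  expect_equal(sc$detection_probability, 1.0)
  expect_equal(sc$false_positive_rate, 0)
  # sub-millisecond timing at this photon budget
  expect_lt(sc$timing_jitter_sd, 1)
})

test_that("flat noise traces yield empty spike sets at default thresholds", {
  # Monte-Carlo null: 1 s shot-noise traces with no events. At the default
  # 4-sigma prominence the expected rate of qualifying noise excursions is
  # a few per hundred seconds, so the large majority of traces are empty.
  empties <- vapply(1:40, function(s) {
    pr <- make_protocol("ap_train", params = list(n_ap = 1, rate_hz = 1,
                                                  tail_ms = 1000))
    pr$command[] <- pr$v_rest        # remove the AP: pure noise
    pr$events <- numeric(0)
    tr <- detrend_dff(render_trace(pr, 2000, seed = s, read_sd = 0))
    nrow(detect_spikes(tr)$events) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.95)
})

test_that("detection is invariant to trace scaling and offset", {
  st <- spike_trace(n_ap = 20, isi_ms = 100, snr = 10, seed = 3)
  sp1 <- detect_spikes(st$trace)
  tr2 <- st$trace
  tr2$dff <- tr2$dff * 7.5 + 0.2
  sp2 <- detect_spikes(tr2)
  expect_equal(sp1$events$time, sp2$events$time)
})

test_that("an exact repeated template is detected at every insertion", {
  set.seed(4)
  n <- 3000
  y <- rnorm(n, 0, 1e-4)
  tmpl <- -c(1, 3, 6, 3, 1) * 0.05
  at <- seq(200, 2800, by = 200)
  for (i in at) y[i + 0:4] <- y[i + 0:4] + tmpl
  tr <- structure(list(time = (seq_len(n) - 1), raw_f = 1000 * (1 + y),
                       lit = rep(TRUE, n),
                       epochs = data.frame(start = 0, end = n),
                       frame_period = 1, baseline = rep(1000, n),
                       dff = y, f0 = 1000),
                  class = "vi_trace")
  sp <- detect_spikes(tr)
  # waveform peak sits at sample index at+2, i.e. time at+1 on this grid
  sc <- score_detection(sp, at + 1, tolerance = 3)
  expect_equal(sc$detection_probability, 1.0)
  expect_true(all(abs(sp$events$time - (at + 1)) <= 1))
})

test_that("detection scoring matches greedily and recovers timing spread", {
  # identical times: probability 1, jitter 0
  sp <- voltim:::empty_spike_set()
  sp$events <- data.frame(time = c(10, 20, 30), frame = 1:3,
                          amplitude = 1, correlation = 1, width_ms = 2)
  sc <- score_detection(sp, c(10, 20, 30), tolerance = 5)
  expect_equal(sc$detection_probability, 1)
  expect_equal(sc$timing_jitter_sd, 0)
  expect_error(score_detection(sp, numeric(0)), "empty")
  # configured jitter is recovered over 500 events
  set.seed(6)
  ref <- seq(100, by = 50, length.out = 500)
  det <- ref + rnorm(500, 0, 0.4)
  sp$events <- data.frame(time = det, frame = seq_along(det),
                          amplitude = 1, correlation = 1, width_ms = 2)
  sc2 <- score_detection(sp, ref, tolerance = 5)
  expect_equal(sc2$timing_jitter_sd, 0.4, tolerance = 0.05)
})

test_that("trial averaging exhibits sqrt-n SNR scaling on iid noise", {
  set.seed(8)
  nf <- 401
  rel <- seq_len(nf) - 1 - 200
  signal <- ifelse(rel >= 0 & rel < 100, -0.04, 0)
  M <- matrix(signal, nf, 50) + matrix(rnorm(nf * 50, 0, 0.01), nf, 50)
  av <- average_trials(M, pre_ms = 200,
                       response_window = c(2, 98),
                       baseline_window = c(-200, -2),
                       n_values = c(1, 25))
  r <- av$snr_vs_n$snr[2] / av$snr_vs_n$snr[1]
  expect_equal(r, 5, tolerance = 0.5)        # sqrt(25) within 10%
  expect_error(average_trials(M[, 1, drop = FALSE]), "2 trials")
})

test_that("latency statistics assign one spike per stimulation pulse", {
  onsets <- seq(0, by = 200, length.out = 10)
  # spikes exactly at onsets
  lj <- latency_jitter(onsets, onsets)
  expect_equal(lj$latency_mean, 0)
  expect_equal(lj$latency_sd, 0)
  # two spikes per pulse: the second is excluded and counted
  sp2 <- sort(c(onsets + 4, onsets + 9))
  lj2 <- latency_jitter(sp2, onsets)
  expect_equal(lj2$n_assigned, 10)
  expect_equal(lj2$n_excluded, 10)
  expect_equal(lj2$latency_mean, 4)
})

test_that("actuation latencies are recovered through the optical pipeline", {
  act <- actuator_model()
  stim <- data.frame(onset = seq(100, by = 200, length.out = 1000),
                     power_density = 0.05)
  ev <- simulate_actuation(act, stim, seed = 9)[[1]]$events
  lj <- latency_jitter(ev, stim$onset)
  expect_equal(lj$latency_mean, 4.3, tolerance = 0.1)
  expect_equal(lj$latency_sd, 1.0, tolerance = 0.15)
})
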