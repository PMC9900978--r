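#' Template-matching spike detection
#'
#' Three-stage detector for negative-going action-potential transients in a
#' dF/F trace:
#' 1. putative peaks: local maxima of `-dff` with topographic prominence of
#'    at least `prominence_sd` baseline sigmas (sigma estimated robustly
#'    from first differences of the trace);
#' 2. template: the mean snippet of the 20 most prominent peaks;
#' 3. matched filtering: sliding normalised cross-correlation of the
#'    template against the trace; events are correlation maxima with
#'    correlation >= `corr_threshold` that coincide with a putative peak
#'    and whose amplitude is at least `amp_frac` of the median seed
#'    amplitude (floored at `prominence_sd` sigmas), with sub-frame event
#'    times from parabolic interpolation of the correlation peak.
#'
#' The detector is invariant to trace scaling and offset. An empty result
#' (no seed peaks) is returned as an empty spike set, not an error.
#'
#' @param trace A detrended [extract_trace()] trace (needs `dff`).
#' @param prominence_sd Stage-1 prominence threshold in baseline-sigma units.
#' @param corr_threshold Stage-3 normalised correlation threshold.
#' @param amp_frac Stage-3 amplitude threshold as a fraction of the median
#'   seed-event amplitude (floored at `prominence_sd` sigmas).
#' @param snippet_halfwidth_ms Template half width (ms).
#' @param seed Unused; kept so scenario configs can carry one seed for all
#'   stages (the detector is deterministic).
#' @return An object of class `spike_set`: data frame `events` with `time`
#'   (ms), `frame`, `amplitude` (-dF/F, positive), `width_ms` (FWHM),
#'   `correlation`; plus `sigma`, `template`.
#' @export
detect_spikes <- function(trace, prominence_sd = 4, corr_threshold = 0.7,
                          amp_frac = 0.5, snippet_halfwidth_ms = 6,
                          seed = NULL) {
  stopifnot(!is.null(trace$dff))
  ok <- which(!is.na(trace$dff))
  y <- -trace$dff[ok]                       # positive-going events
  tm <- trace$time[ok]
  fp <- trace$frame_period
  if (length(y) < 50) return(empty_spike_set())
  sigma <- stats::mad(diff(y)) / sqrt(2)
  if (sigma <= 0) sigma <- stats::sd(y)
  pk <- peak_prominences(y)
  above <- pk$prominence >= prominence_sd * sigma
  if (!any(above)) return(empty_spike_set(sigma = sigma))
  hw <- max(2L, round(snippet_halfwidth_ms / fp))
  ok_pos <- pk$peaks > hw & pk$peaks <= length(y) - hw
  cand_seed <- which(above & ok_pos)
  if (length(cand_seed) == 0) return(empty_spike_set(sigma = sigma))
  # the template comes from the most prominent peaks only
  top <- cand_seed[order(-pk$prominence[cand_seed])]
  top <- top[seq_len(min(20L, length(top)))]
  seeds <- pk$peaks[top]
  snips <- vapply(seeds, function(i) y[(i - hw):(i + hw)],
                  numeric(2 * hw + 1))
  template <- rowMeans(snips)
  template <- template - mean(template)
  # sliding normalised cross-correlation
  nc <- ncc_filter(y, template)
  thr_amp <- max(amp_frac * stats::median(y[seeds]), prominence_sd * sigma)
  cand <- which(nc >= corr_threshold)
  cand <- cand[cand > 1 & cand < length(y)]
  cand <- cand[nc[cand] >= nc[cand - 1] & nc[cand] >= nc[cand + 1]]
  cand <- cand[y[cand] >= thr_amp]
  # template matching confirms putative prominent peaks: a candidate must
  # coincide with a stage-1 peak (within one frame)
  prom_pk <- pk$peaks[above]
  cand <- cand[vapply(cand, function(i)
    any(abs(prom_pk - i) <= 1), logical(1))]
  if (length(cand) == 0) return(empty_spike_set(sigma = sigma))
  # merge candidates closer than the template half width (keep strongest)
  cand <- cand[order(-y[cand])]
  keep <- c()
  for (i in cand) if (all(abs(i - keep) > hw)) keep <- c(keep, i)
  keep <- sort(keep)
  ev <- vapply(keep, function(i) {
    # parabolic interpolation of the correlation peak
    dt_sub <- 0
    if (i > 1 && i < length(y)) {
      a <- nc[i - 1]; b <- nc[i]; cc <- nc[i + 1]
      den <- a - 2 * b + cc
      if (abs(den) > 1e-12) dt_sub <- 0.5 * (a - cc) / den
    }
    c(time = tm[i] + dt_sub * fp, frame = ok[i], amplitude = y[i],
      correlation = nc[i])
  }, numeric(4))
  ev <- as.data.frame(t(ev))
  ev$width_ms <- vapply(keep, function(i) {
    lo <- max(1, i - hw); hi <- min(length(y), i + hw)
    tryCatch(fwhm_1d(tm[lo:hi], pmax(y[lo:hi], 0)), error = function(e) NA_real_)
  }, numeric(1))
  structure(list(events = ev[order(ev$time), ], sigma = sigma,
                 template = template),
            class = "spike_set")
}

empty_spike_set <- function(sigma = NA_real_) {
  structure(list(events = data.frame(time = numeric(0), frame = integer(0),
                                     amplitude = numeric(0),
                                     correlation = numeric(0),
                                     width_ms = numeric(0)),
                 sigma = sigma, template = NULL),
            class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("<spike_set> %d events\n", nrow(x$events)))
  invisible(x)
}

# topographic prominence of all interior local maxima
peak_prominences <- function(y) {
  n <- length(y)
  pks <- which(diff(sign(diff(y))) < 0) + 1L
  prom <- vapply(pks, function(i) {
    lmin <- if (i > 1) {
      j <- i - 1
      m <- y[i]
      while (j >= 1 && y[j] <= y[i]) { m <- min(m, y[j]); j <- j - 1 }
      m
    } else min(y[1:i])
    rmin <- if (i < n) {
      j <- i + 1
      m <- y[i]
      while (j <= n && y[j] <= y[i]) { m <- min(m, y[j]); j <- j + 1 }
      m
    } else min(y[i:n])
    y[i] - max(lmin, rmin)
  }, numeric(1))
  list(peaks = pks, prominence = prom)
}

# normalised cross-correlation of template against the trace (same length
# as y; edges zero)
ncc_filter <- function(y, template) {
  L <- length(template)
  hw <- (L - 1) %/% 2
  tc <- template - mean(template)
  tn <- sqrt(sum(tc^2))
  n <- length(y)
  out <- numeric(n)
  # rolling sums via filter for mean and variance
  ksum <- stats::filter(y, rep(1, L), sides = 2)
  ksq <- stats::filter(y^2, rep(1, L), sides = 2)
  xc <- stats::filter(y, rev(tc), sides = 2)
  valid <- which(!is.na(xc))
  mu <- ksum[valid] / L
  ss <- pmax(ksq[valid] - L * mu^2, 0)
  denom <- sqrt(ss) * tn
  out[valid] <- ifelse(denom > 1e-12, xc[valid] / denom, 0)
  out
}

#' Score detections against reference event times
#'
#' Greedy one-to-one matching of detected to reference events within a
#' tolerance window, in time order.
#'
#' @param spikes A [detect_spikes()] result.
#' @param reference_times Reference (e.g. electrophysiological) event times
#'   (ms); must be non-empty.
#' @param tolerance Matching tolerance (ms).
#' @param duration_s Recording duration (s) for the false-positive rate;
#'   inferred from the reference span if missing.
#' @return An object of class `detection_score`: `detection_probability`,
#'   `timing_jitter_sd` (ms, over matched pairs), `false_positive_rate`
#'   (unmatched detections per second), `matches` data frame.
#' @export
score_detection <- function(spikes, reference_times, tolerance = 5,
                            duration_s = NULL) {
  if (length(reference_times) == 0) stop("reference event times are empty")
  stopifnot(tolerance > 0)
  det <- spikes$events$time
  used <- rep(FALSE, length(det))
  match_det <- rep(NA_integer_, length(reference_times))
  for (j in seq_along(reference_times)) {
    d <- abs(det - reference_times[j])
    d[used] <- Inf
    if (length(d) && min(d) <= tolerance) {
      i <- which.min(d)
      match_det[j] <- i
      used[i] <- TRUE
    }
  }
  matched <- !is.na(match_det)
  dtimes <- det[match_det[matched]]
  jit <- if (sum(matched) >= 2)
    stats::sd(dtimes - reference_times[matched]) else NA_real_
  if (is.null(duration_s))
    duration_s <- (max(reference_times) - min(reference_times) +
                     2 * tolerance) / 1000
  structure(list(
    detection_probability = mean(matched),
    timing_jitter_sd = jit,
    false_positive_rate = sum(!used) / duration_s,
    n_reference = length(reference_times),
    n_detected = length(det),
    matches = data.frame(reference = reference_times,
                         detected = ifelse(matched, dtimes, NA_real_))),
    class = "detection_score")
}

#' Stimulus-aligned trial averaging
#'
#' Averages dF/F responses across trials aligned to stimulus onsets and
#' reports the empirical SNR of the average as a function of the number of
#' trials included.
#'
#' @param trace A detrended trace covering all trials, or a numeric matrix
#'   (frames x trials) of already-aligned responses.
#' @param onsets Stimulus onset times (ms), one per trial (ignored for
#'   matrix input).
#' @param pre_ms,post_ms Window around each onset (ms).
#' @param response_window,baseline_window Times (ms, relative to onset) used
#'   for the per-n SNR: amplitude is `|mean dff|` in the response window,
#'   noise the s.d. in the baseline window.
#' @param n_values Numbers of trials at which to evaluate the SNR.
#' @return List: `time` (ms relative to onset), `mean` (grand average),
#'   `trials` (matrix), `snr_vs_n` (data frame n, snr, amplitude).
#' @export
average_trials <- function(trace, onsets = NULL, pre_ms = 40, post_ms = 60,
                           response_window = c(2, 18),
                           baseline_window = c(-40, -2),
                           n_values = NULL) {
  if (is.matrix(trace)) {
    M <- trace
    rel <- seq_len(nrow(M)) - 1 - pre_ms
  } else {
    stopifnot(!is.null(trace$dff), length(onsets) >= 2)
    fp <- trace$frame_period
    npre <- round(pre_ms / fp); npost <- round(post_ms / fp)
    rel <- (seq_len(npre + npost + 1) - npre - 1) * fp
    M <- vapply(onsets, function(on) {
      i0 <- which.min(abs(trace$time - on))
      idx <- (i0 - npre):(i0 + npost)
      if (min(idx) < 1 || max(idx) > length(trace$dff))
        stop("trial window outside the recording")
      trace$dff[idx]
    }, numeric(npre + npost + 1))
  }
  if (ncol(M) < 2) stop("need at least 2 trials")
  if (is.null(n_values))
    n_values <- unique(pmin(c(1, 5, 10, 25, ncol(M)), ncol(M)))
  rw <- rel >= response_window[1] & rel <= response_window[2]
  bw <- rel >= baseline_window[1] & rel <= baseline_window[2]
  snr <- vapply(n_values, function(n) {
    avg <- rowMeans(M[, seq_len(n), drop = FALSE], na.rm = TRUE)
    amp <- abs(mean(avg[rw], na.rm = TRUE) - mean(avg[bw], na.rm = TRUE))
    noise <- stats::sd(avg[bw], na.rm = TRUE)
    c(amp / noise, amp)
  }, numeric(2))
  list(time = rel, mean = rowMeans(M, na.rm = TRUE), trials = M,
       snr_vs_n = data.frame(n = n_values, snr = snr[1, ],
                             amplitude = snr[2, ]))
}

#' Latency and jitter of evoked spikes
#'
#' Assigns each detected spike to the closest preceding stimulation onset
#' within a window; at most one spike per onset is kept (the first), excess
#' spikes are excluded and counted.
#'
#' @param spikes A [detect_spikes()] result or numeric spike times (ms).
#' @param stim_onsets Stimulation onset times (ms).
#' @param window Maximum latency considered (ms).
#' @return List: `latency_mean`, `latency_sd` (ms), `n_assigned`,
#'   `n_excluded`, `latencies`.
#' @export
latency_jitter <- function(spikes, stim_onsets, window = 30) {
  times <- if (inherits(spikes, "spike_set")) spikes$events$time else spikes
  lat <- rep(NA_real_, length(stim_onsets))
  excluded <- 0L
  for (tsp in sort(times)) {
    j <- findInterval(tsp, stim_onsets)
    if (j < 1) { excluded <- excluded + 1L; next }
    l <- tsp - stim_onsets[j]
    if (l > window || !is.na(lat[j])) excluded <- excluded + 1L
    else lat[j] <- l
  }
  ls <- lat[!is.na(lat)]
  list(latency_mean = mean(ls), latency_sd = stats::sd(ls),
       n_assigned = length(ls), n_excluded = excluded, latencies = lat)
}
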