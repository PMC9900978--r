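#' Stimulation / illumination protocols
#'
#' Builds the voltage-command and illumination-gate time series for the
#' standard characterisation protocols, on a common supersampled time base
#' (`dt`, default 0.1 ms):
#'
#' * `protocol1`: three 100 ms / 100 mV steps under 3 s of continuous
#'   illumination, sampled at 100 Hz (voltage-sensitivity protocol).
#' * `protocol2`: the same three steps, but with 200 ms illumination pulses
#'   centred on each step and 2.5 s dark inter-pulse intervals
#'   (photostability / photorecovery protocol).
#' * `protocol3`: 500 ms continuous illumination with a 20 Hz train of 10
#'   rectangular 100 mV, 3 ms pulses, 1 kHz acquisition (action-potential
#'   surrogate protocol).
#' * `ap_train`: `n_ap` action potentials at `rate_hz` (25-125 Hz trains, or
#'   1 Hz single-AP series), continuous illumination.
#' * `subthreshold`: repeated trials of a 20 ms step of `amplitude_mv`
#'   (0-2.5 mV), strobed 40 ms illumination centred on each step, 1 kHz.
#' * `spontaneous`: Ornstein-Uhlenbeck sub-threshold drive plus Poisson
#'   action potentials under continuous illumination.
#' * `all_optical`: photostimulation pulse train (power, duration, frequency)
#'   with continuous imaging illumination; the voltage command is filled in
#'   by the actuation model downstream.
#'
#' @param kind Protocol name (see above).
#' @param params Named list of overrides; see Details of each kind in the
#'   source. Common entries: `acquisition_rate` (Hz), `v_rest` (mV),
#'   `ap_shape` ("rect" or "triangle"), `ap_width` (ms), `ap_amp` (mV).
#' @param seed Integer seed (used by the stochastic kinds).
#' @param dt Supersample interval (ms), at most 1 ms.
#' @return An object of class `protocol`: `time` (ms, sample centers),
#'   `command` (mV), `gate` (logical illumination), `acquisition_rate`,
#'   `v_rest`, `events` (AP/pulse onset times, ms), `epochs` (data frame of
#'   illumination epochs), `stim` (photostimulation table, all-optical only).
#' @export
make_protocol <- function(kind, params = list(), seed = 1L, dt = 0.1) {
  stopifnot(dt <= 1)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]]
                               else default
  ap_shape <- p("ap_shape", "rect")
  ap_width <- p("ap_width", 3)
  ap_amp <- p("ap_amp", 100)
  out <- switch(
    kind,
    protocol1 = {
      dur <- 3000; v_rest <- p("v_rest", -55)
      tt <- time_base(dur, dt)
      cmd <- rep(v_rest, length(tt))
      onsets <- c(500, 1500, 2500)
      for (on in onsets) cmd[tt >= on & tt < on + 100] <- v_rest + 100
      list(time = tt, command = cmd, gate = rep(TRUE, length(tt)),
           acquisition_rate = p("acquisition_rate", 100), v_rest = v_rest,
           events = onsets)
    },
    protocol2 = {
      v_rest <- p("v_rest", -55)
      dark <- p("dark_ms", 2500)
      n_ep <- p("n_epochs", 3)
      starts <- 100 + (seq_len(n_ep) - 1) * (200 + dark)
      dur <- starts[n_ep] + 200 + 100
      tt <- time_base(dur, dt)
      cmd <- rep(v_rest, length(tt))
      gate <- rep(FALSE, length(tt))
      onsets <- starts + 50
      for (k in seq_len(n_ep)) {
        gate[tt >= starts[k] & tt < starts[k] + 200] <- TRUE
        cmd[tt >= onsets[k] & tt < onsets[k] + 100] <- v_rest + 100
      }
      list(time = tt, command = cmd, gate = gate,
           acquisition_rate = p("acquisition_rate", 100), v_rest = v_rest,
           events = onsets)
    },
    protocol3 = {
      v_rest <- p("v_rest", -75)
      dur <- 520
      tt <- time_base(dur, dt)
      cmd <- rep(v_rest, length(tt))
      gate <- tt >= 10 & tt < 510
      onsets <- 30 + 50 * 0:9
      for (on in onsets) cmd[tt >= on & tt < on + 3] <- v_rest + 100
      list(time = tt, command = cmd, gate = gate,
           acquisition_rate = p("acquisition_rate", 1000), v_rest = v_rest,
           events = onsets)
    },
    ap_train = {
      v_rest <- p("v_rest", -75)
      rate_hz <- p("rate_hz", 100)
      n_ap <- p("n_ap", 10)
      isi <- 1000 / rate_hz
      onsets <- 30 + isi * (seq_len(n_ap) - 1)
      dur <- max(onsets) + p("tail_ms", 60)
      tt <- time_base(dur, dt)
      cmd <- rep(v_rest, length(tt))
      for (on in onsets)
        cmd <- cmd + ap_wave(tt, on, ap_shape, ap_width, ap_amp)
      list(time = tt, command = cmd, gate = rep(TRUE, length(tt)),
           acquisition_rate = p("acquisition_rate", 1000), v_rest = v_rest,
           events = onsets)
    },
    subthreshold = {
      v_rest <- p("v_rest", -75)
      amp <- p("amplitude_mv", 1)
      n_trials <- p("n_trials", 50)
      trial_ms <- p("trial_ms", 100)
      dur <- n_trials * trial_ms
      tt <- time_base(dur, dt)
      cmd <- rep(v_rest, length(tt))
      gate <- rep(FALSE, length(tt))
      onsets <- (seq_len(n_trials) - 1) * trial_ms + 40
      for (on in onsets) {
        cmd[tt >= on & tt < on + 20] <- v_rest + amp
        gate[tt >= on - 10 & tt < on + 30] <- TRUE
      }
      list(time = tt, command = cmd, gate = gate,
           acquisition_rate = p("acquisition_rate", 1000), v_rest = v_rest,
           events = onsets)
    },
    spontaneous = {
      v_rest <- p("v_rest", -65)
      dur <- p("duration_ms", 30000)
      theta <- p("ou_theta", 1 / 50)      # mean-reversion rate (1/ms)
      sigma <- p("ou_sigma", 2)           # stationary s.d. (mV)
      rate <- p("ap_rate_hz", 5)
      refract <- p("refractory_ms", 20)
      tt <- time_base(dur, dt)
      n <- length(tt)
      with_seed(seed, {
        # exact OU discretisation
        a <- exp(-theta * dt)
        innov <- stats::rnorm(n, 0, sigma * sqrt(1 - a^2))
        v <- numeric(n); x <- 0
        for (i in seq_len(n)) { x <- a * x + innov[i]; v[i] <- x }
        cand <- which(stats::runif(n) < rate * dt / 1000)
        onsets <- c()
        last <- -Inf
        for (i in cand) {
          if (tt[i] - last >= refract) { onsets <- c(onsets, tt[i]); last <- tt[i] }
        }
        cmd <- v_rest + v
        for (on in onsets)
          cmd <- cmd + ap_wave(tt, on, ap_shape, ap_width, ap_amp)
        list(time = tt, command = cmd, gate = rep(TRUE, n),
             acquisition_rate = p("acquisition_rate", 1000), v_rest = v_rest,
             events = onsets)
      })
    },
    all_optical = {
      v_rest <- p("v_rest", -75)
      n_pulses <- p("n_pulses", 5)
      freq <- p("freq_hz", 5)
      pulse_ms <- p("pulse_ms", 15)
      power <- p("power_density", 0.03)
      isi <- 1000 / freq
      onsets <- 100 + isi * (seq_len(n_pulses) - 1)
      dur <- max(onsets) + isi
      tt <- time_base(dur, dt)
      list(time = tt, command = rep(v_rest, length(tt)),
           gate = rep(TRUE, length(tt)),
           acquisition_rate = p("acquisition_rate", 1000), v_rest = v_rest,
           events = numeric(0),
           stim = data.frame(onset = onsets, duration = pulse_ms,
                             power_density = power))
    },
    stop(sprintf("unknown protocol kind '%s'", kind))
  )
  out$kind <- kind
  out$dt <- dt
  out$seed <- seed
  out$ap_shape <- ap_shape; out$ap_width <- ap_width; out$ap_amp <- ap_amp
  out$epochs <- gate_epochs(out$time, out$gate, dt)
  class(out) <- "protocol"
  out
}

# stylised action-potential waveform added to the command trace
ap_wave <- function(tt, onset, shape = "rect", width = 3, amp = 100) {
  tr <- tt - onset
  switch(shape,
    rect = ifelse(tr >= 0 & tr < width, amp, 0),
    triangle = {
      rise <- 0.3 * width
      ifelse(tr >= 0 & tr < rise, amp * tr / rise,
        ifelse(tr >= rise & tr < width, amp * (width - tr) / (width - rise), 0))
    },
    stop("unknown AP shape"))
}

time_base <- function(duration, dt) seq(dt / 2, duration - dt / 2, by = dt)

# contiguous TRUE runs of the gate as start/end times (ms)
gate_epochs <- function(tt, gate, dt) {
  r <- rle(gate)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  k <- which(r$values)
  data.frame(start = tt[starts[k]] - dt / 2, end = tt[ends[k]] + dt / 2)
}

#' Insert action potentials into a protocol's voltage command
#'
#' Used by the all-optical scenarios to add actuation-evoked spikes to a
#' cell's command trace.
#'
#' @param protocol A `protocol`.
#' @param event_times AP onset times (ms).
#' @return A modified copy with `command` updated and `events` replaced.
#' @export
add_events <- function(protocol, event_times) {
  cmd <- protocol$command
  for (on in event_times)
    cmd <- cmd + ap_wave(protocol$time, on, protocol$ap_shape,
                         protocol$ap_width, protocol$ap_amp)
  protocol$command <- cmd
  protocol$events <- sort(event_times)
  protocol
}
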