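#' Voltage-indicator sensor model
#'
#' Linearised model of a negative-going genetically encoded voltage
#' indicator: fractional fluorescence change is
#' `sensitivity * (V - V_rest) / 100` filtered by first-order
#' activation/deactivation kinetics. The default sensitivity (-0.43 per
#' 100 mV) matches the steady-state calibration; the kinetic time constants
#' are calibrated so that the frame-integrated peak response to a 3 ms /
#' 100 mV action-potential surrogate is about -30% dF/F0 at 1 kHz and -27%
#' at 500 Hz.
#'
#' Photobleaching is double-exponential in cumulative illuminated time with
#' rates scaling as `(power / reference)^bleach_power_exponent`; the fast
#' component refills to at most `recovery_fraction` of its original
#' amplitude across each dark interval, the slow component is permanent.
#'
#' @param sensitivity dF/F per 100 mV depolarisation (negative).
#' @param tau_on,tau_off Activation / deactivation time constants (ms).
#' @param bleach_fast_tau,bleach_slow_tau Bleaching time constants (s of
#'   illuminated time, at the reference power density).
#' @param bleach_fast_frac Fraction of fluorescence in the fast
#'   (recoverable) bleaching pool.
#' @param recovery_fraction Maximum refill level of the fast pool after a
#'   dark interval, in `[0, 1]`.
#' @param bleach_power_exponent Power-density exponent of the bleach rates
#'   (2 for a two-photon process).
#' @param reference_density Power density (mW/um^2) at which the bleach
#'   taus are quoted.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(sensitivity = -0.43, tau_on = 2.1, tau_off = 2.5,
                         bleach_fast_tau = 1.0, bleach_slow_tau = 100,
                         bleach_fast_frac = 0.2, recovery_fraction = 0.97,
                         bleach_power_exponent = 2,
                         reference_density = 1.33) {
  stopifnot(sensitivity < 0, tau_on > 0, tau_off > 0,
            bleach_fast_tau > 0, bleach_slow_tau > 0,
            bleach_fast_frac >= 0, bleach_fast_frac <= 1,
            recovery_fraction >= 0, recovery_fraction <= 1)
  structure(as.list(environment()), class = "sensor_model")
}

#' Fluorescence response to a voltage trace
#'
#' Applies the linear sensitivity and first-order on/off kinetics to a
#' supersampled voltage command. Depolarisation gives a negative-going
#' dF/F; the activation time constant applies while the response magnitude
#' grows, the deactivation constant while it relaxes.
#'
#' @param voltage Voltage time series (mV) at steps of `dt`.
#' @param dt Sample interval (ms), at most 1 ms.
#' @param sensor A [sensor_model()].
#' @param v_rest Resting potential (mV).
#' @return dF/F time series (unitless, negative-going).
#' @export
voltage_to_dff <- function(voltage, dt, sensor = sensor_model(),
                           v_rest = voltage[1]) {
  stopifnot(dt <= 1)
  target <- sensor$sensitivity * (voltage - v_rest) / 100
  a_on <- dt / sensor$tau_on
  a_off <- dt / sensor$tau_off
  out <- numeric(length(voltage))
  state <- 0
  for (i in seq_along(voltage)) {
    a <- if (abs(target[i]) > abs(state)) a_on else a_off
    state <- state + a * (target[i] - state)
    out[i] <- state
  }
  out
}

# Bleach factor per frame. lit_ms: illuminated ms accumulated in each frame
# interval (0 when dark). Returns the multiplicative bleach factor at each
# frame, applying dark-interval recovery of the fast pool.
bleach_factors <- function(lit_ms, sensor, power_density) {
  scale <- (power_density / sensor$reference_density)^
    sensor$bleach_power_exponent
  kf <- scale / (sensor$bleach_fast_tau * 1000)   # per ms
  ks <- scale / (sensor$bleach_slow_tau * 1000)
  Af <- sensor$bleach_fast_frac
  vf <- 1; vs <- 1
  dark_run <- FALSE
  out <- numeric(length(lit_ms))
  for (i in seq_along(lit_ms)) {
    if (lit_ms[i] > 0) {
      if (dark_run) {                             # dark interval just ended
        vf <- max(vf, sensor$recovery_fraction)
        dark_run <- FALSE
      }
      vf <- vf * exp(-kf * lit_ms[i])
      vs <- vs * exp(-ks * lit_ms[i])
    } else dark_run <- TRUE
    out[i] <- Af * vf + (1 - Af) * vs
  }
  out
}
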