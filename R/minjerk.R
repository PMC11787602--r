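# Minimum-jerk trajectory primitives.
#
# Position along the chord: s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5,
# tau = t / T in [0, 1]; speed v(tau) = 30 (A/T) tau^2 (1 - tau)^2 peaks at
# 15 A / (8 T) at tau = 1/2, and v / v_peak = 16 tau^2 (1 - tau)^2, which
# inverts in closed form on the ascending branch.

#' Minimum-jerk position and speed
#'
#' @param tau Normalised time in `[0, 1]` (values outside are clamped).
#' @param amplitude Movement amplitude (cm).
#' @param duration Movement duration (s or ms; speed comes out per that unit).
#' @return `minjerk_position()`: distance travelled along the chord;
#'   `minjerk_speed()`: tangential speed.
#' @export
minjerk_position <- function(tau, amplitude = 1) {
  tau <- pmin(pmax(tau, 0), 1)
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' @rdname minjerk_position
#' @export
minjerk_speed <- function(tau, amplitude = 1, duration = 1) {
  tau <- pmin(pmax(tau, 0), 1)
  30 * (amplitude / duration) * tau^2 * (1 - tau)^2
}

#' Peak speed of a minimum-jerk movement
#' @param amplitude,duration Movement amplitude and duration.
#' @return `15 * amplitude / (8 * duration)`, attained at the midpoint.
#' @export
minjerk_peak_speed <- function(amplitude, duration) 15 * amplitude / (8 * duration)

# Ascending-branch tau at which speed reaches `frac` of peak:
# 16 tau^2 (1-tau)^2 = frac  =>  tau(1-tau) = sqrt(frac)/4.
minjerk_tau_at_frac <- function(frac) {
  stopifnot(all(frac >= 0 & frac <= 1))
  s <- sqrt(frac) / 4
  (1 - sqrt(pmax(1 - 4 * s, 0))) / 2
}

# Tau at which the travelled fraction of the amplitude reaches `pfrac`
# (monotone; inverted by root-bracketing on a fine grid with interpolation).
minjerk_tau_at_position <- function(pfrac) {
  grid <- seq(0, 1, length.out = 2001)
  sgrid <- minjerk_position(grid)
  approx(sgrid, grid, xout = pmin(pmax(pfrac, 0), 1), ties = "ordered")$y
}

# Closed-form noise-free landmarks of one reach, in ms after the go-cue.
#
# `rt` is the *detected* onset latency (first crossing of
# `onset_speed_threshold`), `duration` the detected onset-to-tap time. The
# underlying minimum-jerk duration T satisfies T * (1 - tau_on(T)) = duration
# and is recovered by fixed-point iteration (tau_on depends on T only through
# the peak speed).
minjerk_landmarks <- function(rt, duration, amplitude,
                              onset_speed_threshold = 5,
                              phase_velocity_fraction = 0.85,
                              condition = "self_touch",
                              trigger_margin = 0.05) {
  n <- max(length(rt), length(duration))
  rt <- rep_len(rt, n)
  duration <- rep_len(duration, n)
  T_total <- duration # ms
  tau_on <- 0
  for (i in 1:6) {
    vpk <- minjerk_peak_speed(amplitude, T_total / 1000) # cm/s
    u <- pmin(onset_speed_threshold / vpk, 1)
    tau_on <- minjerk_tau_at_frac(u)
    T_total <- duration / (1 - tau_on)
  }
  tau_a <- minjerk_tau_at_frac(phase_velocity_fraction)
  tau_d <- 1 - tau_a
  start <- rt - tau_on * T_total # true movement start (ms after go-cue)
  end <- start + T_total         # tap / contact
  offset <- if (condition == "self_touch") {
    end
  } else {
    start + minjerk_tau_at_position(1 - trigger_margin / amplitude) * T_total
  }
  list(
    movement_start = start,
    t_total = T_total,
    onset = rt,
    offset = offset,
    movement_duration = offset - rt,
    peak_time = start + 0.5 * T_total,
    peak_speed = minjerk_peak_speed(amplitude, T_total / 1000),
    ascend85 = start + tau_a * T_total,
    descend85 = start + tau_d * T_total
  )
}
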