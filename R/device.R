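#' Define an active-echo device
#'
#' Models the catheter-mounted piezo element and its electronics: receive
#' gain, threshold comparator with per-line latch, firing with a loop delay,
#' blink (time-modulation) gating, frequency-modulated pulse settings, and a
#' directivity pattern about the cylinder axis. The pulser is limited to
#' 150 V drive and a minimum 12.5 ns pulse duration.
#'
#' @param position Element position `c(x, e, z)` in metres.
#' @param orientation Cylinder-axis unit vector (default along the
#'   elevational axis: catheter perpendicular to the image plane).
#' @param rx_gain_db Receiver gain in dB (default 19).
#' @param threshold Trigger threshold in volts (must be > 0).
#' @param loop_delay Electronic receive-to-fire latency in seconds
#'   (default 0.6 us).
#' @param pulse_freq Active-echo pulse frequency in Hz (default 9 MHz,
#'   distinct from a 10 MHz imaging carrier so matched filtering can
#'   discriminate the two).
#' @param pulse_cycles Cycles in the fired Gabor pulse.
#' @param drive_voltage Pulser voltage in volts, in `(0, 150]`.
#' @param blink_period Blink period in seconds (default 0.5, i.e. 2 Hz).
#' @param blink_duty On-fraction of the blink cycle, in `(0, 1)`.
#' @param mode Operating mode: `"off"`, `"echo"` (retransmit on trigger) or
#'   `"pattern"` (fire a planned pattern).
#' @param sensitivity Receive sensitivity, volts per unit beacon pressure.
#' @param directivity_floor Floor of the `cos^2` directivity factor.
#' @return An object of class `ae_device`.
#' @export
ae_device <- function(position = c(0, 0, 0.04), orientation = c(0, 1, 0),
                      rx_gain_db = 19, threshold = 0.05,
                      loop_delay = 0.6e-6, pulse_freq = 9e6, pulse_cycles = 2,
                      drive_voltage = 58, blink_period = 0.5, blink_duty = 0.5,
                      mode = c("echo", "pattern", "off"), sensitivity = 1,
                      directivity_floor = 0.05) {
  mode <- match.arg(mode)
  if (threshold <= 0) stop("trigger threshold must be > 0", call. = FALSE)
  if (drive_voltage <= 0 || drive_voltage > 150) {
    stop("drive_voltage must be in (0, 150] volts", call. = FALSE)
  }
  if (pulse_cycles / pulse_freq < 12.5e-9) {
    stop("pulse duration below the 12.5 ns pulser limit", call. = FALSE)
  }
  if (blink_duty <= 0 || blink_duty >= 1) stop("blink_duty must be in (0, 1)", call. = FALSE)
  if (blink_period <= 0) stop("blink_period must be > 0", call. = FALSE)
  if (!is.finite(rx_gain_db)) stop("rx_gain_db must be finite", call. = FALSE)
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(
    list(position = position, orientation = orientation,
         rx_gain_db = rx_gain_db, threshold = threshold,
         loop_delay = loop_delay, pulse_freq = pulse_freq,
         pulse_cycles = pulse_cycles, drive_voltage = drive_voltage,
         blink_period = blink_period, blink_duty = blink_duty,
         mode = mode, sensitivity = sensitivity,
         directivity_floor = directivity_floor),
    class = "ae_device"
  )
}

#' @export
print.ae_device <- function(x, ...) {
  cat(sprintf(
    "Active-echo device [%s]: at (%.1f, %.1f, %.1f) mm, gain %g dB, threshold %g V\n",
    x$mode, x$position[1] * 1e3, x$position[2] * 1e3, x$position[3] * 1e3,
    x$rx_gain_db, x$threshold
  ))
  cat(sprintf("  loop delay %.2f us, pulse %.1f MHz x %d cycles, drive %g V, blink %g s @ %g%%\n",
              x$loop_delay * 1e6, x$pulse_freq / 1e6, x$pulse_cycles,
              x$drive_voltage, x$blink_period, 100 * x$blink_duty))
  invisible(x)
}

#' Beam incidence angle on the element
#'
#' Angle between the (axially travelling) beam and the plane perpendicular to
#' the element's cylinder axis; 0 degrees means the beam hits the cylinder
#' broadside (maximum sensitivity).
#'
#' @param device An [ae_device()].
#' @return Angle in degrees.
#' @export
incidence_angle <- function(device) {
  asin(min(1, abs(device$orientation[3]))) * 180 / pi
}

#' Directivity factor of the element
#'
#' A smooth, even pattern, maximal (1) at broadside incidence and floored at
#' `directivity_floor` so the element remains usable (with gain adjustment)
#' at every tested angle: `max(cos^2(angle), floor)`.
#'
#' @param angle_deg Incidence angle(s) in degrees (see [incidence_angle()]).
#' @param device An [ae_device()] (only the floor is read); may be `NULL`.
#' @return Factor(s) in (0, 1].
#' @export
directivity_factor <- function(angle_deg, device = NULL) {
  fl <- if (is.null(device)) 0.05 else device$directivity_floor
  pmax(cos(angle_deg * pi / 180)^2, fl)
}

#' Received voltage for a beacon pressure amplitude
#'
#' `pressure * sensitivity * 10^(rx_gain_db / 20) * directivity`.
#'
#' @param pressure Beacon pressure amplitude(s) (unitless field scale).
#' @param device An [ae_device()].
#' @return Voltage(s) in volts.
#' @export
receive_voltage <- function(pressure, device) {
  if (any(pressure < 0)) stop("pressure amplitude must be >= 0", call. = FALSE)
  pressure * device$sensitivity * 10^(device$rx_gain_db / 20) *
    directivity_factor(incidence_angle(device), device)
}

#' Threshold comparator with latch over a voltage trace
#'
#' Emits a trigger event at the first sample where `|v| >= threshold`; the
#' latch then blocks further events until it is reset at the next line start,
#' so at most one event per line is possible. Returns `NULL` when the trace
#' never crosses the threshold.
#'
#' @param trace Sampled voltage trace over one line.
#' @param threshold Threshold in volts (> 0).
#' @param fs Sampling rate of the trace in Hz.
#' @return A list `(sample, t_trigger, amplitude_v)` of class
#'   `trigger_event`, or `NULL`.
#' @export
trigger_decision <- function(trace, threshold, fs) {
  if (threshold <= 0) stop("trigger threshold must be > 0", call. = FALSE)
  idx <- which(abs(trace) >= threshold)
  if (length(idx) == 0) return(NULL)
  i <- idx[1]
  structure(
    list(sample = i, t_trigger = (i - 1) / fs, amplitude_v = trace[i]),
    class = "trigger_event"
  )
}

#' Blink (time-modulation) gate
#'
#' The signal processor periodically enables/disables the active-echo
#' feedback so the spot blinks against the tissue background. Enabled iff
#' `(t mod blink_period) < blink_duty * blink_period`.
#'
#' @param t Absolute time(s) in seconds.
#' @param device An [ae_device()].
#' @return Logical vector.
#' @export
blink_gate <- function(t, device) {
  (t %% device$blink_period) < device$blink_duty * device$blink_period
}

#' Build an active-echo firing from a trigger event
#'
#' Fire time is the trigger time plus the electronic loop delay; the waveform
#' is a Gabor pulse at the device's pulse frequency and cycle count with
#' amplitude proportional to the drive voltage (150 V drive corresponds to
#' unit waveform amplitude).
#'
#' @param event A `trigger_event` (see [trigger_decision()]).
#' @param device An [ae_device()].
#' @param fs Sampling rate for the waveform in Hz.
#' @return A list `(fire_time, waveform, amplitude)` of class `ae_firing`.
#' @export
make_firing <- function(event, device, fs) {
  if (device$pulse_cycles / device$pulse_freq < 12.5e-9) {
    stop("pulse duration below the 12.5 ns pulser limit", call. = FALSE)
  }
  structure(
    list(fire_time = event$t_trigger + device$loop_delay,
         waveform = gabor_pulse(fs, device$pulse_freq, device$pulse_cycles,
                                amplitude = device$drive_voltage / 150),
         amplitude = 1),
    class = "ae_firing"
  )
}

#' Analog front-end band-pass filter
#'
#' The receive chain's analog filters (0.1-20 MHz pass band) applied to a
#' sampled trace before trigger comparison.
#'
#' @param trace Sampled voltage trace.
#' @param fs Sampling rate in Hz.
#' @param band Pass band `c(low, high)` in Hz.
#' @return Filtered trace.
#' @export
front_end_filter <- function(trace, fs, band = c(0.1e6, 20e6)) {
  bandpass_fft(trace, fs, band)
}
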