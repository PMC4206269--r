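#' Zero-phase band-pass filter via FFT
#'
#' Frequency-domain band-pass with raised-cosine (cos^2) transition edges of
#' width `transition`. The filter is exactly linear and zero phase, which the
#' scanner relies on: superposition of scene and active-echo contributions
#' holds to rounding error, and symmetric pulses keep their envelope peak on
#' the same sample. The smooth edges keep time-domain ringing short (a hard
#' brick wall would smear every packet into long sinc tails).
#'
#' @param x Real sample vector.
#' @param fs Sampling rate in Hz.
#' @param band Pass band `c(low, high)` in Hz.
#' @param transition Edge transition width in Hz.
#' @return Filtered vector of the same length.
#' @export
bandpass_fft <- function(x, fs, band, transition = 1e6) {
  n <- length(x)
  if (n == 0) return(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f) # fold to [0, fs/2]
  w <- numeric(n)
  w[f >= band[1] & f <= band[2]] <- 1
  lo_ramp <- f > band[1] - transition & f < band[1]
  w[lo_ramp] <- cos((band[1] - f[lo_ramp]) / transition * pi / 2)^2
  hi_ramp <- f > band[2] & f < band[2] + transition
  w[hi_ramp] <- cos((f[hi_ramp] - band[2]) / transition * pi / 2)^2
  Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
}

# Add pulse samples centred at (possibly fractional-rounded) sample index.
add_packet <- function(line, pulse_samples, center_index, scale) {
  m <- length(pulse_samples)
  c0 <- (m + 1) / 2
  lo <- center_index - floor((m - 1) / 2)
  hi <- lo + m - 1
  n <- length(line)
  src <- max(1, 1 - lo + 1):min(m, n - lo + 1)
  if (length(src) == 0 || src[1] > src[length(src)]) return(line)
  dst <- (lo:hi)[src]
  line[dst] <- line[dst] + scale * pulse_samples[src]
  line
}

#' Synthesize one RF line
#'
#' Sums (a) scatterer echoes: a transmit-pulse replica centred at the
#' round-trip time `2 * one_way_time(z)`, scaled by the beam amplitude at the
#' scatterer, its reflectivity and the return-path attenuation; and (b)
#' active-echo packets arriving at `fire_time + slant travel time` from the
#' element to this line's aperture centre. The sum is band-pass filtered to
#' the probe's receive band. In harmonic mode, tissue echoes are rendered at
#' twice the transmit frequency scaled by the probe's `harmonic_fraction`
#' (band bookkeeping only).
#'
#' @param probe A [linear_probe()].
#' @param scn A [scene()].
#' @param line_x Lateral centre of this line in metres.
#' @param firings List of `ae_firing` objects (see [make_firing()]), fire
#'   times in seconds within the line window.
#' @param profile A [beam_profile()].
#' @param element_pos Element position `c(x, e, z)` for the firings (may be
#'   `NULL` when there are none).
#' @return Numeric RF sample vector of length `n_rf_samples`.
#' @export
synthesize_rf_line <- function(probe, scn, line_x, firings = list(),
                               profile, element_pos = NULL) {
  med <- scn$medium
  n <- n_rf_samples(probe, med)
  line <- numeric(n)
  tx_f0 <- if (probe$harmonic) 2 * probe$f0_tx else probe$f0_tx
  tx_scale <- if (probe$harmonic) probe$harmonic_fraction else 1
  pulse <- gabor_pulse(probe$fs, tx_f0, probe$tx_cycles)

  sc <- scn$scatterers
  if (!is.null(sc) && nrow(sc$positions) > 0) {
    pos <- sc$positions
    z <- pos[, 3]
    ok <- z > 0 & z <= probe$max_depth
    if (any(ok)) {
      sx <- lateral_sigma(profile, z[ok])
      keep <- which(ok)[abs(pos[ok, 1] - line_x) <= 4 * sx &
                          abs(pos[ok, 2]) <= 4 * profile$elev_sigma]
      for (i in keep) {
        zi <- pos[i, 3]
        amp <- beam_amplitude(probe, profile, line_x, pos[i, ], med) *
          sc$reflectivities[i] *
          attenuation_factor(zi, tx_f0, med) * tx_scale
        t_rt <- 2 * one_way_time(zi, med)
        line <- add_packet(line, pulse$samples, round(t_rt * probe$fs) + 1, amp)
      }
    }
  }

  for (fr in firings) {
    if (fr$fire_time < 0 || fr$fire_time >= probe$line_period) {
      stop("active-echo firing outside the line window", call. = FALSE)
    }
    d <- sqrt(sum((element_pos - c(line_x, 0, 0))^2))
    t_arr <- fr$fire_time + slant_one_way_time(d, element_pos[3], med)
    att <- attenuation_factor(element_pos[3], fr$waveform$f0, med,
                              path_scale = if (element_pos[3] > 0) d / element_pos[3] else 1)
    # receive-aperture sensitivity: an unfocused whole-array acceptance
    # (sigma = array_width / 4). Wide enough that pixels injected on distant
    # lines stay bright, yet the line nearest the element records the
    # strongest packet, so the plain echo spot sits on the element's line.
    sx_rx <- probe$n_elements * probe$pitch / 4
    rx_w <- exp(-(element_pos[1] - line_x)^2 / (2 * sx_rx^2)) *
      exp(-element_pos[2]^2 / (2 * profile$elev_sigma^2))
    line <- add_packet(line, fr$waveform$samples, round(t_arr * probe$fs) + 1,
                       fr$amplitude * att * rx_w)
  }

  bandpass_fft(line, probe$fs, probe$rx_band)
}

rf_frame <- function(samples, probe, med, frame_start, line_x) {
  structure(
    list(samples = samples, fs = probe$fs, line_x = line_x,
         frame_start = frame_start, assumed_c = med$assumed_c,
         line_period = probe$line_period),
    class = "rf_frame"
  )
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("RF frame: %d lines x %d samples at %.0f MHz (start %.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs / 1e6, x$frame_start))
  invisible(x)
}

trigger_log <- function(events, frame_index) {
  structure(list(events = events, frame_index = frame_index,
                 count = nrow(events)),
            class = "trigger_log")
}

#' @export
print.trigger_log <- function(x, ...) {
  cat(sprintf("Trigger log, frame %d: %d trigger(s)\n", x$frame_index, x$count))
  if (x$count > 0) print(utils::head(x$events, 10), row.names = FALSE)
  invisible(x)
}

#' Acquire one B-mode frame with the active-echo event loop
#'
#' Runs the coupled acquisition loop, line by line in firing order. For each
#' line: the beacon amplitude at the element is evaluated (beam model plus
#' receive chain); a trigger is latched when the received peak voltage
#' reaches the threshold, timestamped at the beacon arrival (the slant
#' travel time from the line's aperture centre to the element); if the
#' device mode and blink gate permit, an echo firing at
#' `trigger time + loop_delay` (echo mode) or the plan's firings for this
#' line (pattern mode) are added; finally the RF line is synthesized. At
#' most one trigger per line is possible (one beacon per line; the
#' comparator latch resets at every line start).
#'
#' The comparator timing is idealized to the beacon pulse centre, so
#' echo-mode fire times exceed the beacon arrival by exactly `loop_delay`
#' (see the package vignette for the sampled-trace comparator,
#' [trigger_decision()]).
#'
#' @param probe A [linear_probe()].
#' @param scn A [scene()].
#' @param device An [ae_device()] or `NULL`.
#' @param plan A `firing_plan` (see [rasterize_sync()]) when the device is in
#'   pattern mode.
#' @param profile A [beam_profile()]; defaults to `beam_profile(probe)`.
#' @param frame_start Absolute start time of the frame in seconds (drives the
#'   blink gate).
#' @param frame_index Frame number recorded in the trigger log.
#' @param compute_rf If `FALSE`, skip RF synthesis (trigger log only) --
#'   used by sweeps and parameter grids where only counts and amplitudes
#'   matter.
#' @return A list with `frame` (an `rf_frame`, or `NULL` when
#'   `compute_rf = FALSE`), `log` (a `trigger_log`) and `firings` (per-line
#'   list of `ae_firing`s actually emitted).
#' @export
acquire_frame <- function(probe, scn, device = NULL, plan = NULL,
                          profile = NULL, frame_start = 0, frame_index = 1,
                          compute_rf = TRUE) {
  stopifnot(inherits(probe, "linear_probe"), inherits(scn, "scene"))
  med <- scn$medium
  if (probe$line_period <= 2 * probe$max_depth / med$assumed_c) {
    stop("line_period must exceed the deepest round trip", call. = FALSE)
  }
  if (is.null(profile)) profile <- beam_profile(probe)
  sched <- line_schedule(probe)
  L <- nrow(sched)
  firings <- vector("list", L)
  events <- data.frame(line = integer(0), t_trigger = numeric(0),
                       amplitude_v = numeric(0))

  if (!is.null(device) && device$mode != "off") {
    pos <- device$position
    if (pos[3] <= 0 || pos[3] > probe$max_depth) {
      stop("device position outside the imaged region", call. = FALSE)
    }
    if (!is.null(plan)) {
      if (any(plan$firings$line > L) || any(plan$firings$line < 1)) {
        stop("firing plan references a line outside the frame", call. = FALSE)
      }
    }
    amps <- beam_amplitude(probe, profile, sched$line_x, pos, med)
    v <- receive_voltage(amps, device)
    d <- sqrt((pos[1] - sched$line_x)^2 + pos[2]^2 + pos[3]^2)
    t_beacon <- vapply(d, slant_one_way_time, numeric(1), z = pos[3], med = med)
    triggered <- v >= device$threshold
    gate <- blink_gate(frame_start + sched$t_start, device)
    if (any(triggered)) {
      events <- data.frame(line = sched$line[triggered],
                           t_trigger = t_beacon[triggered],
                           amplitude_v = v[triggered])
    }
    if (device$mode == "echo") {
      for (l in which(triggered & gate)) {
        ev <- structure(list(sample = NA_integer_, t_trigger = t_beacon[l],
                             amplitude_v = v[l]), class = "trigger_event")
        firings[[l]] <- list(make_firing(ev, device, probe$fs))
      }
    } else if (device$mode == "pattern" && !is.null(plan)) {
      for (i in seq_len(nrow(plan$firings))) {
        l <- plan$firings$line[i]
        if (!gate[l]) next
        fr <- structure(
          list(fire_time = plan$firings$t[i],
               waveform = gabor_pulse(probe$fs, device$pulse_freq,
                                      device$pulse_cycles,
                                      amplitude = device$drive_voltage / 150 *
                                        plan$firings$amplitude[i]),
               amplitude = 1),
          class = "ae_firing")
        firings[[l]] <- c(firings[[l]], list(fr))
      }
    }
  }

  frame <- NULL
  if (compute_rf) {
    n <- n_rf_samples(probe, med)
    samples <- matrix(0, nrow = L, ncol = n)
    for (l in seq_len(L)) {
      samples[l, ] <- synthesize_rf_line(
        probe, scn, sched$line_x[l], firings[[l]] %||% list(), profile,
        element_pos = if (!is.null(device)) device$position else NULL
      )
    }
    frame <- rf_frame(samples, probe, med, frame_start, sched$line_x)
  }

  list(frame = frame, log = trigger_log(events, frame_index),
       firings = firings)
}
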