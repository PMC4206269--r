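#' Imaging mode presets
#'
#' Clinical scanners expose mode presets that change the transmit frequency
#' and receive band. The presets here only do the frequency/band bookkeeping:
#' in harmonic mode the tissue echoes are rendered at twice the transmit
#' frequency, scaled by `harmonic_fraction`, and no nonlinear propagation is
#' modeled.
#'
#' @param name One of `"general"`, `"resolution"`, `"penetration"`,
#'   `"harmonic"`.
#' @return A list with `f0_tx`, `rx_band`, `harmonic`, `harmonic_fraction`.
#' @export
imaging_mode <- function(name = c("general", "resolution", "penetration", "harmonic")) {
  name <- match.arg(name)
  switch(name,
    general     = list(name = name, f0_tx = 10e6, rx_band = c(7e6, 13e6),
                       harmonic = FALSE, harmonic_fraction = 1),
    resolution  = list(name = name, f0_tx = 10e6, rx_band = c(8.5e6, 14.5e6),
                       harmonic = FALSE, harmonic_fraction = 1),
    penetration = list(name = name, f0_tx = 6.6e6, rx_band = c(4e6, 9e6),
                       harmonic = FALSE, harmonic_fraction = 1),
    harmonic    = list(name = name, f0_tx = 5e6, rx_band = c(8e6, 12e6),
                       harmonic = TRUE, harmonic_fraction = 0.1)
  )
}

#' Define a linear-array imaging probe
#'
#' Geometry and acquisition parameters of the simulated linear array. The
#' defaults describe a 128-element probe firing 256 RF lines per frame with a
#' 32-element transmit aperture focused at 4 cm. Receive is modeled as a
#' single pre-beamformed RF line per transmit event.
#'
#' @param n_elements Number of array elements.
#' @param pitch Element pitch in metres.
#' @param f0_tx Transmit centre frequency in Hz.
#' @param rx_band Receive band `c(low, high)` in Hz.
#' @param fs RF sampling rate in Hz (must exceed twice the receive band top).
#' @param lines_per_frame Number of A-lines per frame.
#' @param tx_aperture Transmit aperture in elements (`<= n_elements`).
#' @param focus_depth Transmit focal depth in metres, or `NA`/`"none"` for an
#'   unfocused beam.
#' @param tx_power Unitless transmit power scale.
#' @param line_period Time allotted to one A-line in seconds (must exceed the
#'   deepest round trip).
#' @param max_depth Imaging depth in metres.
#' @param tx_cycles Cycles in the Gabor transmit pulse.
#' @param frame_rate Optional display frame rate (Hz) for multi-frame runs;
#'   when `NULL`, frames abut at `lines_per_frame * line_period`.
#' @param mode Optional imaging-mode preset name (see [imaging_mode()]);
#'   overrides `f0_tx` and `rx_band`.
#' @return An object of class `linear_probe`.
#' @export
linear_probe <- function(n_elements = 128, pitch = 0.3e-3,
                         f0_tx = 10e6, rx_band = c(7e6, 13e6), fs = 40e6,
                         lines_per_frame = 256, tx_aperture = 32,
                         focus_depth = 0.04, tx_power = 1,
                         line_period = 200e-6, max_depth = 0.05,
                         tx_cycles = 2, frame_rate = NULL, mode = NULL) {
  harmonic <- FALSE
  harmonic_fraction <- 1
  if (!is.null(mode)) {
    preset <- imaging_mode(mode)
    f0_tx <- preset$f0_tx
    rx_band <- preset$rx_band
    harmonic <- preset$harmonic
    harmonic_fraction <- preset$harmonic_fraction
  }
  if (identical(focus_depth, "none")) focus_depth <- NA_real_
  if (lines_per_frame < 1) stop("lines_per_frame must be >= 1", call. = FALSE)
  if (tx_aperture > n_elements) stop("tx_aperture cannot exceed n_elements", call. = FALSE)
  if (fs <= 2 * rx_band[2]) stop("fs must exceed twice the receive band top", call. = FALSE)
  if (line_period <= 0 || max_depth <= 0) stop("line_period and max_depth must be > 0", call. = FALSE)
  structure(
    list(n_elements = n_elements, pitch = pitch, f0_tx = f0_tx,
         rx_band = rx_band, fs = fs, lines_per_frame = lines_per_frame,
         tx_aperture = tx_aperture, focus_depth = focus_depth,
         tx_power = tx_power, line_period = line_period,
         max_depth = max_depth, tx_cycles = tx_cycles,
         frame_rate = frame_rate, mode = mode %||% "general",
         harmonic = harmonic, harmonic_fraction = harmonic_fraction),
    class = "linear_probe"
  )
}

#' @export
print.linear_probe <- function(x, ...) {
  cat(sprintf(
    "Linear probe: %d elements (pitch %.2f mm), %d lines/frame, Tx %.1f MHz %s\n",
    x$n_elements, x$pitch * 1e3, x$lines_per_frame, x$f0_tx / 1e6,
    if (is.na(x$focus_depth)) "unfocused"
    else sprintf("focused at %.0f mm", x$focus_depth * 1e3)
  ))
  cat(sprintf("  Rx band %.1f-%.1f MHz, fs %.0f MHz, depth %.0f mm, line period %.0f us\n",
              x$rx_band[1] / 1e6, x$rx_band[2] / 1e6, x$fs / 1e6,
              x$max_depth * 1e3, x$line_period * 1e6))
  invisible(x)
}

#' A-line schedule of a frame
#'
#' Lines are laid out uniformly across the array footprint (centred on
#' `x = 0`) and fired in order, one every `line_period` seconds.
#'
#' @param probe A [linear_probe()].
#' @return A `data.frame` with `line` (1-based index), `line_x` (lateral beam
#'   centre, metres) and `t_start` (seconds from frame start).
#' @export
line_schedule <- function(probe) {
  stopifnot(inherits(probe, "linear_probe"))
  L <- probe$lines_per_frame
  width <- probe$n_elements * probe$pitch
  spacing <- width / L
  data.frame(
    line = seq_len(L),
    line_x = (seq_len(L) - (L + 1) / 2) * spacing,
    t_start = (seq_len(L) - 1) * probe$line_period
  )
}

# Number of RF samples per line for a given display speed of sound.
n_rf_samples <- function(probe, med) {
  round(2 * probe$max_depth / med$assumed_c * probe$fs)
}

#' Gabor pulse (Gaussian-windowed cosine)
#'
#' The transmit and active-echo pulse model. The pulse is centred on its
#' middle sample (envelope peak at the centre), with Gaussian standard
#' deviation `duration/4` where `duration = cycles/f0`, tabulated out to
#' `+/- duration` so the truncated tails are at the `exp(-8)` level.
#'
#' @param fs Sampling rate in Hz.
#' @param f0 Carrier frequency in Hz.
#' @param cycles Number of carrier cycles in the nominal duration.
#' @param amplitude Peak amplitude.
#' @return A list with `samples`, `center` (index of the centre sample),
#'   `fs`, `f0` and `duration` (seconds), of class `gabor_pulse`.
#' @export
gabor_pulse <- function(fs, f0, cycles = 2, amplitude = 1) {
  duration <- cycles / f0
  sigma <- duration / 4
  n2 <- ceiling(duration * fs)
  t <- (-n2:n2) / fs
  structure(
    list(samples = amplitude * exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * f0 * t),
         center = n2 + 1, fs = fs, f0 = f0, duration = duration,
         amplitude = amplitude),
    class = "gabor_pulse"
  )
}
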