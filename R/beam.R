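#' Transmit beam profile
#'
#' A separable Gaussian beam model. Laterally, an unfocused aperture has a
#' constant width `sigma = aperture_width / 4`; a focused aperture follows a
#' hyperbolic waist with minimum `lambda * focus_depth / aperture_width` at
#' the focus and Rayleigh range `pi * w0^2 / lambda`. Elevationally the beam
#' is Gaussian with a constant `elev_sigma` (no elevation lens model); the
#' elevational width is what mid-plane detection ultimately measures. The
#' on-axis peak amplitude encodes transmit power and, for a focused beam, the
#' focusing gain `sqrt(sigma_unfocused / sigma(z))`.
#'
#' @param probe A [linear_probe()].
#' @param elev_sigma Elevational Gaussian sigma in metres (default 3 mm).
#' @param c_ref Speed of sound used for the wavelength (default 1540 m/s).
#' @return An object of class `beam_profile`.
#' @export
beam_profile <- function(probe, elev_sigma = 3e-3, c_ref = 1540) {
  stopifnot(inherits(probe, "linear_probe"))
  if (elev_sigma <= 0) stop("elev_sigma must be > 0", call. = FALSE)
  aw <- probe$tx_aperture * probe$pitch
  lambda <- c_ref / probe$f0_tx
  focused <- !is.na(probe$focus_depth)
  w0 <- if (focused) lambda * probe$focus_depth / aw else NA_real_
  structure(
    list(focused = focused, aperture_width = aw, lambda = lambda,
         sigma_unf = aw / 4, w0 = w0,
         zR = if (focused) pi * w0^2 / lambda else NA_real_,
         focus_depth = probe$focus_depth, elev_sigma = elev_sigma,
         tx_power = probe$tx_power, tx_aperture = probe$tx_aperture),
    class = "beam_profile"
  )
}

#' Lateral beam sigma at depth
#' @param profile A [beam_profile()].
#' @param z Depth(s) in metres.
#' @return Sigma(s) in metres.
#' @export
lateral_sigma <- function(profile, z) {
  if (!profile$focused) return(rep(profile$sigma_unf, length(z)))
  profile$w0 * sqrt(1 + ((z - profile$focus_depth) / profile$zR)^2)
}

#' On-axis peak beam amplitude at depth
#'
#' `tx_power * (tx_aperture / 32)` scaled, for a focused beam, by the
#' focusing gain `sqrt(sigma_unfocused / sigma(z))` (maximal at the focus).
#' The 32-element aperture is the reference.
#'
#' @param profile A [beam_profile()].
#' @param z Depth(s) in metres.
#' @return Unitless amplitude(s).
#' @export
peak_amplitude <- function(profile, z) {
  base <- profile$tx_power * (profile$tx_aperture / 32)
  if (!profile$focused) return(rep(base, length(z)))
  base * sqrt(profile$sigma_unf / lateral_sigma(profile, z))
}

#' Beam amplitude at a field point
#'
#' The beacon pressure amplitude a point `(x, e, z)` sees when the line
#' centred at `line_x` fires:
#' `peak_amplitude(z) * exp(-(x - line_x)^2 / (2 sigma_x(z)^2)) *`
#' `exp(-e^2 / (2 sigma_e^2))`, times the one-way attenuation to depth `z`
#' at the transmit frequency when a medium is supplied. Vectorized over
#' `line_x`.
#'
#' @param probe A [linear_probe()].
#' @param profile A [beam_profile()].
#' @param line_x Lateral beam centre(s) in metres.
#' @param point Field point `c(x, e, z)` in metres; `z` must be in
#'   `(0, max_depth]`.
#' @param med Optional [medium()] for attenuation.
#' @return Unitless amplitude(s), one per `line_x`.
#' @export
beam_amplitude <- function(probe, profile, line_x, point, med = NULL) {
  x <- point[1]; e <- point[2]; z <- point[3]
  if (z <= 0) stop("field point must have depth z > 0", call. = FALSE)
  if (z > probe$max_depth) stop("field point deeper than max_depth", call. = FALSE)
  sx <- lateral_sigma(profile, z)
  amp <- peak_amplitude(profile, z) *
    exp(-(x - line_x)^2 / (2 * sx^2)) *
    exp(-e^2 / (2 * profile$elev_sigma^2))
  if (!is.null(med)) amp <- amp * attenuation_factor(z, probe$f0_tx, med)
  amp
}
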