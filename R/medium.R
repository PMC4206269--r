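#' Define an acoustic medium, possibly layered along the axial axis
#'
#' A medium is an ordered stack of layers along the axial (depth) axis `z`,
#' each with a thickness, a speed of sound and a frequency-dependent
#' attenuation coefficient. The scanner renders depth with its own
#' `assumed_c` (the display speed of sound), which is how a fast intermediate
#' layer (e.g. aluminium between probe and tool) makes a target appear
#' shallower than it really is.
#'
#' Propagation is straight-ray: refraction at layer boundaries is ignored, and
#' attenuation is a frequency-dependent amplitude factor
#' `10^(-alpha * f_MHz * path_cm / 20)` per traversed layer, with no
#' dispersion.
#'
#' @param layers A `data.frame` with columns `thickness` (m; the last layer may
#'   be `Inf`), `c` (speed of sound, m/s) and `attenuation` (dB/(cm*MHz)).
#'   If `NULL`, a single unbounded layer is built from `c` and `attenuation`.
#' @param c Speed of sound (m/s) for the single-layer shorthand.
#' @param attenuation Attenuation (dB/(cm*MHz)) for the single-layer shorthand.
#' @param assumed_c Display speed of sound used by the scanner to map time to
#'   depth; defaults to the first layer's `c`.
#' @return An object of class `medium`.
#' @examples
#' water <- medium(c = 1480)
#' stack <- medium(layers = data.frame(
#'   thickness = c(20e-3, 25.4e-3, Inf),
#'   c = c(1480, 6320, 1480),
#'   attenuation = 0
#' ), assumed_c = 1480)
#' @export
medium <- function(layers = NULL, c = 1540, attenuation = 0, assumed_c = NULL) {
  if (is.null(layers)) {
    layers <- data.frame(thickness = Inf, c = c, attenuation = attenuation)
  }
  layers <- as.data.frame(layers)
  need <- c("thickness", "c", "attenuation")
  if (!all(need %in% names(layers))) {
    stop("medium layers need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  n <- nrow(layers)
  if (n < 1) stop("medium needs at least one layer", call. = FALSE)
  if (any(layers$thickness[-n] <= 0) || !is.finite(sum(layers$thickness[-n])) ||
      layers$thickness[n] <= 0) {
    stop("layer thicknesses must be > 0 (only the last layer may be unbounded)",
         call. = FALSE)
  }
  if (any(layers$c <= 0)) stop("speed of sound must be > 0", call. = FALSE)
  if (any(layers$attenuation < 0)) stop("attenuation must be >= 0", call. = FALSE)
  structure(
    list(layers = layers, assumed_c = assumed_c %||% layers$c[1]),
    class = "medium"
  )
}

#' @export
print.medium <- function(x, ...) {
  cat("Acoustic medium:", nrow(x$layers), "layer(s), display c =",
      x$assumed_c, "m/s\n")
  print(x$layers, row.names = FALSE)
  invisible(x)
}

# Axial path length through each layer for a target at depth z (vector z ok).
layer_segments <- function(z, med) {
  th <- med$layers$thickness
  tops <- cumsum(c(0, th[-length(th)]))
  seg <- vapply(z, function(zi) pmax(0, pmin(zi - tops, th)), numeric(length(th)))
  matrix(seg, nrow = length(th))
}

#' One-way travel time to an axial depth
#'
#' Sums path/c over the traversed layers; for a single-layer medium this is
#' `z/c`.
#'
#' @param z Axial depth(s) in metres, `>= 0`.
#' @param med A [medium()].
#' @return Travel time(s) in seconds.
#' @export
one_way_time <- function(z, med) {
  stopifnot(inherits(med, "medium"))
  if (any(z < 0)) stop("depth must be >= 0", call. = FALSE)
  total <- sum(med$layers$thickness)
  if (is.finite(total) && any(z > total + 1e-12)) {
    stop("depth beyond the modeled region (last layer is bounded)", call. = FALSE)
  }
  seg <- layer_segments(z, med) # layers x length(z)
  colSums(seg / med$layers$c)
}

#' Travel time along a slant straight-ray path
#'
#' For a straight path of Euclidean length `d` ending at axial depth `z`, each
#' layer's axial segment is stretched by `d/z`. Reduces to [one_way_time()]
#' when `d == z`, and to `d/c` of the first layer when `z == 0`.
#'
#' @param d Path length in metres.
#' @param z Axial depth of the endpoint in metres.
#' @param med A [medium()].
#' @return Travel time in seconds.
#' @export
slant_one_way_time <- function(d, z, med) {
  if (z <= 0) return(d / med$layers$c[1])
  one_way_time(z, med) * (d / z)
}

#' Amplitude attenuation factor along an axial (or slant) path
#'
#' One-way amplitude factor `prod_i 10^(-alpha_i * f_MHz * path_i_cm / 20)`
#' over the traversed layers.
#'
#' @param z Axial depth(s) in metres.
#' @param f Frequency in Hz.
#' @param med A [medium()].
#' @param path_scale Multiplier on each axial segment (e.g. `d/z` for a slant
#'   path, `2` for round trip).
#' @return Amplitude factor(s) in (0, 1].
#' @export
attenuation_factor <- function(z, f, med, path_scale = 1) {
  stopifnot(inherits(med, "medium"))
  if (all(med$layers$attenuation == 0)) return(rep(1, length(z)))
  seg <- layer_segments(z, med) # layers x length(z)
  db <- med$layers$attenuation * (f / 1e6) * (seg * path_scale * 100)
  10^(-colSums(db) / 20)
}

#' Apparent (displayed) depth for a round-trip time
#'
#' The scanner maps a round-trip time to depth with its display speed of
#' sound: `assumed_c * t / 2`. In a homogeneous medium with
#' `assumed_c == c` this is the true depth; with a fast intermediate layer the
#' target appears shallower than it is.
#'
#' @param t Round-trip time(s) in seconds, `>= 0`.
#' @param med A [medium()].
#' @return Apparent depth(s) in metres.
#' @export
apparent_depth <- function(t, med) {
  stopifnot(inherits(med, "medium"))
  if (any(t < 0)) stop("round-trip time must be >= 0", call. = FALSE)
  med$assumed_c * t / 2
}
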