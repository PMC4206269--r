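#' Specify a random scatterer phantom
#'
#' Describes the tissue-mimicking background of a scene: a box of point
#' scatterers at a given volumetric density with reflectivities drawn from a
#' named distribution family, plus optional bright spherical inclusions
#' (scatterers inside an inclusion get their reflectivity multiplied).
#'
#' Coordinates follow the package convention: `x` lateral (along the array),
#' `e` elevational (out of the image plane; the image mid-plane is `e = 0`),
#' `z` axial (depth, 0 at the probe face).
#'
#' @param x_range,e_range,z_range Length-2 numeric ranges (metres) of the box.
#' @param density Scatterers per cm^3 (`>= 0`).
#' @param reflectivity A list naming the amplitude distribution:
#'   `list(family = "rayleigh", scale = 1)`,
#'   `list(family = "uniform", min = , max = )`, or
#'   `list(family = "lognormal", meanlog = , sdlog = )`.
#' @param inclusions Optional list of `list(center = c(x, e, z), radius = ,
#'   amplitude = )` bright inclusions.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(x_range = c(-20e-3, 20e-3),
                         e_range = c(-5e-3, 5e-3),
                         z_range = c(5e-3, 50e-3),
                         density = 50,
                         reflectivity = list(family = "rayleigh", scale = 1),
                         inclusions = NULL) {
  rng <- list(x = sort(as.numeric(x_range)), e = sort(as.numeric(e_range)),
              z = sort(as.numeric(z_range)))
  ext <- vapply(rng, diff, numeric(1))
  if (any(ext <= 0)) stop("phantom extents must be > 0", call. = FALSE)
  if (density < 0) stop("scatterer density must be >= 0", call. = FALSE)
  structure(
    list(x_range = rng$x, e_range = rng$e, z_range = rng$z,
         density = density, reflectivity = reflectivity,
         inclusions = inclusions),
    class = "phantom_spec"
  )
}

#' Realize a scatterer field from a phantom specification
#'
#' Draws `round(density * volume_cm3)` scatterers uniformly in the box with
#' reflectivities from the spec's named family. The same `(spec, seed)` pair
#' always reproduces the identical field; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return An object of class `scatterer_field` with a `positions` matrix
#'   (n x 3 columns `x`, `e`, `z`), `reflectivities`, `seed` and `spec`.
#' @export
make_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(seed) != 1 || is.na(seed)) stop("a single integer seed is required", call. = FALSE)
  vol_cm3 <- prod(
    diff(spec$x_range), diff(spec$e_range), diff(spec$z_range)
  ) * 1e6
  n <- round(spec$density * vol_cm3)
  field <- with_seed(seed, {
    pos <- cbind(
      x = stats::runif(n, spec$x_range[1], spec$x_range[2]),
      e = stats::runif(n, spec$e_range[1], spec$e_range[2]),
      z = stats::runif(n, spec$z_range[1], spec$z_range[2])
    )
    refl <- draw_reflectivity(spec$reflectivity, n)
    list(pos = pos, refl = refl)
  })
  pos <- field$pos
  refl <- field$refl
  for (inc in spec$inclusions %||% list()) {
    d2 <- (pos[, 1] - inc$center[1])^2 + (pos[, 2] - inc$center[2])^2 +
      (pos[, 3] - inc$center[3])^2
    refl[d2 <= inc$radius^2] <- refl[d2 <= inc$radius^2] * inc$amplitude
  }
  structure(
    list(positions = pos, reflectivities = refl, seed = seed, spec = spec),
    class = "scatterer_field"
  )
}

draw_reflectivity <- function(ref, n) {
  fam <- ref$family %||% "rayleigh"
  r <- switch(fam,
    rayleigh = (ref$scale %||% 1) * sqrt(-2 * log(stats::runif(n))),
    uniform = stats::runif(n, ref$min %||% 0, ref$max %||% 1),
    lognormal = stats::rlnorm(n, ref$meanlog %||% 0, ref$sdlog %||% 0.5),
    stop("unknown reflectivity family '", fam, "'", call. = FALSE)
  )
  if (n == 0) numeric(0) else r
}

#' @export
print.scatterer_field <- function(x, ...) {
  cat("Scatterer field:", nrow(x$positions), "scatterers (seed", x$seed, ")\n")
  invisible(x)
}

#' Bundle a medium and a scatterer field into a scene
#'
#' @param med A [medium()].
#' @param scatterers A [make_phantom()] result, or `NULL` for an anechoic
#'   (water-tank-like) scene.
#' @return An object of class `scene`.
#' @export
scene <- function(med, scatterers = NULL) {
  stopifnot(inherits(med, "medium"))
  if (!is.null(scatterers)) stopifnot(inherits(scatterers, "scatterer_field"))
  structure(list(medium = med, scatterers = scatterers), class = "scene")
}
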