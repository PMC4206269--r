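#' Parse a physical quantity with an optional unit suffix
#'
#' Scenario configuration files may give lengths, times and frequencies with
#' explicit unit suffixes (`"40 mm"`, `"200 us"`, `"10 MHz"`). Internally the
#' package works in SI units (metres, seconds, hertz) throughout;
#' `parse_quantity()` normalizes a config value to SI. Bare numbers are
#' returned unchanged (assumed already SI).
#'
#' @param x A numeric value, or a character scalar/vector like `"40 mm"`.
#' @param key Optional config key name, used in error messages.
#' @return Numeric value(s) in SI units.
#' @examples
#' parse_quantity("25.4 mm")
#' parse_quantity("10 MHz")
#' @export
parse_quantity <- function(x, key = NULL) {
  if (is.numeric(x)) return(x)
  if (!is.character(x)) {
    stop("cannot interpret value", if (!is.null(key)) paste0(" for key '", key, "'"), call. = FALSE)
  }
  scales <- c(
    m = 1, mm = 1e-3, cm = 1e-2, um = 1e-6, nm = 1e-9,
    s = 1, ms = 1e-3, us = 1e-6, ns = 1e-9,
    hz = 1, khz = 1e3, mhz = 1e6,
    v = 1, db = 1, fps = 1
  )
  vapply(x, function(xi) {
    m <- regmatches(xi, regexec("^\\s*([-+0-9.eE]+)\\s*([a-zA-Z]*)\\s*$", xi))[[1]]
    bad <- function() stop(
      "cannot parse quantity '", xi, "'",
      if (!is.null(key)) paste0(" for key '", key, "'"),
      call. = FALSE
    )
    if (length(m) != 3) bad()
    val <- suppressWarnings(as.numeric(m[2]))
    if (is.na(val)) bad()
    unit <- tolower(m[3])
    if (!nzchar(unit)) return(val)
    if (!unit %in% names(scales)) {
      stop(
        "unknown unit '", m[3], "' in '", xi, "'",
        if (!is.null(key)) paste0(" for key '", key, "'"),
        call. = FALSE
      )
    }
    val * scales[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
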