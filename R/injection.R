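#' Specify a virtual pattern
#'
#' A pattern is a set of virtual pixels. With `anchor = "absolute"` each
#' pixel is an image coordinate: a 1-based A-line index and a depth in
#' metres. With `anchor = "element_relative"` each pixel is an offset from
#' the element's own image position: a line offset `dline` and a depth
#' offset `ddepth` (metres), so the pattern moves with the element.
#'
#' @param pixels A `data.frame` with columns `line`, `depth`, `intensity`
#'   (absolute) or `dline`, `ddepth`, `intensity` (element-relative).
#'   Intensities must be in `(0, 1]`.
#' @param anchor `"absolute"` or `"element_relative"`.
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(pixels, anchor = c("absolute", "element_relative")) {
  anchor <- match.arg(anchor)
  pixels <- as.data.frame(pixels)
  need <- if (anchor == "absolute") c("line", "depth", "intensity")
          else c("dline", "ddepth", "intensity")
  if (nrow(pixels) > 0) {
    if (!all(need %in% names(pixels))) {
      stop("pattern pixels need columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(pixels$intensity <= 0 | pixels$intensity > 1)) {
      stop("pixel intensities must be in (0, 1]", call. = FALSE)
    }
    if (anchor == "absolute" && any(pixels$depth <= 0)) {
      stop("pixel depths must be > 0", call. = FALSE)
    }
  }
  structure(list(pixels = pixels, anchor = anchor), class = "pattern_spec")
}

#' Build an absolute pattern from a text bitmap
#'
#' Rows of a character bitmap (e.g. `c("#.#", "###", "#.#")`) become pixels:
#' columns map to A-lines and rows map to depths.
#'
#' @param rows Character vector; each string is one bitmap row (shallow
#'   first).
#' @param line0 A-line of the first bitmap column.
#' @param depth0 Depth (m) of the first bitmap row.
#' @param dline Line step per bitmap column.
#' @param ddepth Depth step (m) per bitmap row.
#' @param on_char Character marking an "on" pixel.
#' @param intensity Intensity of on pixels.
#' @return A [pattern_spec()] with `anchor = "absolute"`.
#' @export
pattern_from_bitmap <- function(rows, line0, depth0, dline = 1,
                                ddepth = 1e-3, on_char = "#", intensity = 1) {
  px <- do.call(rbind, lapply(seq_along(rows), function(r) {
    chars <- strsplit(rows[r], "")[[1]]
    on <- which(chars == on_char)
    if (length(on) == 0) return(NULL)
    data.frame(line = line0 + (on - 1) * dline,
               depth = depth0 + (r - 1) * ddepth,
               intensity = intensity)
  }))
  pattern_spec(px %||% data.frame(line = integer(0), depth = numeric(0),
                                  intensity = numeric(0)), "absolute")
}

firing_plan <- function(firings, method, skipped = NULL) {
  structure(list(firings = firings, method = method,
                 skipped = skipped %||% data.frame()),
            class = "firing_plan")
}

#' @export
print.firing_plan <- function(x, ...) {
  cat(sprintf("Firing plan (%s): %d firing(s), %d pixel(s) skipped\n",
              x$method, nrow(x$firings), nrow(x$skipped)))
  invisible(x)
}

#' Fire time for a virtual pixel
#'
#' To paint a virtual pixel at depth `y` on the line being acquired, the
#' element at distance `d` from the line's receiving aperture centre must
#' fire at `t = 2*y/c - d/c` after the line start: the displayed round-trip
#' delay `2*y/c` minus the element-to-probe travel time `d/c`. A pixel with
#' `2*y < d` is unreachable (the sound cannot arrive early enough).
#'
#' @param y Pixel depth(s) in metres.
#' @param d Euclidean distance(s) from the element to the line's aperture
#'   centre, metres. Alternatively supply `element_pos` and `line_x`.
#' @param c Speed of sound in m/s.
#' @param element_pos Optional element position `c(x, e, z)` used to compute
#'   `d` when `d` is missing.
#' @param line_x Lateral centre of the target line (with `element_pos`).
#' @return Fire time(s) in seconds after line start.
#' @export
pixel_fire_time <- function(y, d = NULL, c = 1540, element_pos = NULL,
                            line_x = NULL) {
  if (is.null(d)) {
    if (is.null(element_pos) || is.null(line_x)) {
      stop("supply either d or element_pos + line_x", call. = FALSE)
    }
    d <- sqrt((element_pos[1] - line_x)^2 + element_pos[2]^2 + element_pos[3]^2)
  }
  t <- (2 * y - d) / c
  if (any(t < 0)) {
    stop("unreachable pixel: 2*y < d (would require firing before line start)",
         call. = FALSE)
  }
  t
}

# Sort by (line, t) and merge firings closer than min_gap on the same line.
finalize_plan <- function(fir, skipped, method, min_gap) {
  if (nrow(fir) > 0) {
    fir <- fir[order(fir$line, fir$t), , drop = FALSE]
    if (min_gap > 0 && nrow(fir) > 1) {
      keep <- rep(TRUE, nrow(fir))
      i <- 1
      for (j in 2:nrow(fir)) {
        if (fir$line[j] == fir$line[i] && fir$t[j] - fir$t[i] < min_gap) {
          fir$amplitude[i] <- min(1, fir$amplitude[i] + fir$amplitude[j])
          keep[j] <- FALSE
        } else i <- j
      }
      fir <- fir[keep, , drop = FALSE]
    }
    rownames(fir) <- NULL
  }
  if (nrow(skipped) > 0) {
    warning(sprintf("%d unreachable pixel(s) skipped", nrow(skipped)),
            call. = FALSE)
  }
  firing_plan(fir, method, skipped)
}

#' Rasterize an absolute pattern using frame synchronization (method 1)
#'
#' With a frame synchronization signal available, the element-to-aperture
#' distance `d` for every target line follows from geometry, and each pixel
#' maps to one firing at [pixel_fire_time()] on its line. Unreachable pixels
#' (fire time before line start) and pixels past the line window are skipped
#' with a warning, not an error.
#'
#' @param pattern A [pattern_spec()] with `anchor = "absolute"`.
#' @param probe A [linear_probe()].
#' @param element_pos Element position `c(x, e, z)` in metres.
#' @param c Speed of sound in m/s.
#' @param min_gap Minimum spacing between firings on one line (seconds);
#'   closer pixels are merged with summed intensity. Typically the pulse
#'   duration.
#' @return A `firing_plan` with `method = "sync"`.
#' @export
rasterize_sync <- function(pattern, probe, element_pos, c = 1540,
                           min_gap = 0) {
  stopifnot(inherits(pattern, "pattern_spec"))
  if (pattern$anchor != "absolute") {
    stop("rasterize_sync needs an absolute-anchored pattern", call. = FALSE)
  }
  sched <- line_schedule(probe)
  px <- pattern$pixels
  fir <- data.frame(line = integer(0), t = numeric(0), amplitude = numeric(0))
  skipped <- fir
  for (i in seq_len(nrow(px))) {
    l <- px$line[i]
    if (l < 1 || l > nrow(sched)) {
      skipped <- rbind(skipped, data.frame(line = l, t = NA, amplitude = px$intensity[i]))
      next
    }
    d <- sqrt((element_pos[1] - sched$line_x[l])^2 + element_pos[2]^2 +
                element_pos[3]^2)
    t <- (2 * px$depth[i] - d) / c
    if (t < 0 || t >= probe$line_period) {
      skipped <- rbind(skipped, data.frame(line = l, t = t, amplitude = px$intensity[i]))
      next
    }
    fir <- rbind(fir, data.frame(line = l, t = t, amplitude = px$intensity[i]))
  }
  finalize_plan(fir, skipped, "sync", min_gap)
}

#' Estimate the A-line period from trigger times (method 2 front half)
#'
#' When no synchronization signal is available, the element still receives
#' beacons from several neighbouring lines; successive trigger times are
#' (integer multiples of) the A-line period apart. The estimate is the
#' median of successive differences after dividing each difference by its
#' nearest-integer line gap. The base period used for the integer snapping
#' is the smallest positive difference, or `base_period` when supplied
#' (e.g. carried over from an earlier frame).
#'
#' @param times Absolute trigger times in seconds (>= 2).
#' @param base_period Optional prior base period in seconds.
#' @return Estimated line period in seconds.
#' @export
estimate_line_period <- function(times, base_period = NULL) {
  times <- sort(times)
  d <- diff(times)
  d <- d[d > 1e-12]
  if (length(d) < 1) {
    stop("insufficient data: need at least two distinct trigger times",
         call. = FALSE)
  }
  base <- base_period %||% min(d)
  gaps <- pmax(1, round(d / base))
  stats::median(d / gaps)
}

#' Rasterize an element-relative pattern from a reference trigger (method 2)
#'
#' Without frame synchronization, the received beacon itself is the clock: a
#' pixel at `(dline, ddepth)` relative to the element becomes a firing on
#' line `ref_line + dline` at `ref trigger time + 2*ddepth/c` within that
#' line (realized as a delay of `dline * period + offset` from the reference
#' trigger). The `(0, 0)` pixel fires at the beacon arrival itself and lands
#' on the element's own position, consistent with plain echo mode.
#'
#' @param pattern A [pattern_spec()] with `anchor = "element_relative"`.
#' @param period Estimated A-line period in seconds (see
#'   [estimate_line_period()]).
#' @param ref_event Reference trigger: a list with `line` and `t_trigger`
#'   (time within that line).
#' @param probe A [linear_probe()].
#' @param c Speed of sound in m/s.
#' @param min_gap Minimum spacing between firings on one line (seconds).
#' @return A `firing_plan` with `method = "period-estimate"`.
#' @export
rasterize_relative <- function(pattern, period, ref_event, probe, c = 1540,
                               min_gap = 0) {
  stopifnot(inherits(pattern, "pattern_spec"))
  if (pattern$anchor != "element_relative") {
    stop("rasterize_relative needs an element-relative pattern", call. = FALSE)
  }
  px <- pattern$pixels
  L <- probe$lines_per_frame
  fir <- data.frame(line = integer(0), t = numeric(0), amplitude = numeric(0))
  skipped <- fir
  for (i in seq_len(nrow(px))) {
    l <- ref_event$line + px$dline[i]
    t <- ref_event$t_trigger + 2 * px$ddepth[i] / c
    if (l < 1 || l > L || t < 0 || t >= probe$line_period) {
      skipped <- rbind(skipped, data.frame(line = l, t = t,
                                           amplitude = px$intensity[i]))
      next
    }
    # realized as a delay of (dline * period + within-line offset) after the
    # reference trigger; stored per line for the acquisition loop
    fir <- rbind(fir, data.frame(line = l, t = t, amplitude = px$intensity[i]))
  }
  finalize_plan(fir, skipped, "period-estimate", min_gap)
}

#' Mid-plane indicator bars from a trigger count
#'
#' Renders the frame trigger count as a stack of virtual bars next to the
#' element (`ceil(count / counts_per_bar)` bars): the closer the element is
#' to the image mid-plane, the higher the count and the more bars appear.
#'
#' @param trigger_count Non-negative integer trigger count.
#' @param counts_per_bar Triggers represented by one bar.
#' @param bar_halfwidth_lines Half-width of each bar in lines.
#' @param start_ddepth Depth offset (m) of the first bar below the element.
#' @param bar_spacing Depth spacing (m) between bars.
#' @param intensity Bar pixel intensity.
#' @return A [pattern_spec()] with `anchor = "element_relative"` (empty for
#'   a zero count).
#' @export
midplane_bars <- function(trigger_count, counts_per_bar = 5,
                          bar_halfwidth_lines = 2, start_ddepth = 5e-3,
                          bar_spacing = 2e-3, intensity = 1) {
  if (trigger_count < 0) stop("trigger_count must be >= 0", call. = FALSE)
  n_bars <- ceiling(trigger_count / counts_per_bar)
  if (n_bars == 0) {
    return(pattern_spec(data.frame(dline = integer(0), ddepth = numeric(0),
                                   intensity = numeric(0)),
                        "element_relative"))
  }
  px <- do.call(rbind, lapply(seq_len(n_bars), function(k) {
    data.frame(dline = -bar_halfwidth_lines:bar_halfwidth_lines,
               ddepth = start_ddepth + (k - 1) * bar_spacing,
               intensity = intensity)
  }))
  pattern_spec(px, "element_relative")
}
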