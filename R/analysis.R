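#' Acquire an active-echo waveform template by frame subtraction
#'
#' The matched-filter template is obtained by subtracting RF frames acquired
#' with the active echo enabled and disabled over an otherwise identical
#' (same seed) scene. Because the scanner is linear, the difference is
#' exactly the active-echo contribution; the template is the difference
#' restricted to its energy-containing support (samples above 1% of the
#' difference maximum) on the most energetic line.
#'
#' @param frame_on,frame_off `rf_frame`s from the same scene with the device
#'   toggled.
#' @return A list of class `ae_template` with `samples`, `line`,
#'   `start_sample` and `fs`.
#' @export
acquire_template <- function(frame_on, frame_off) {
  stopifnot(inherits(frame_on, "rf_frame"), inherits(frame_off, "rf_frame"))
  d <- frame_on$samples - frame_off$samples
  m <- max(abs(d))
  if (m == 0) stop("no differential signal: the frames are identical", call. = FALSE)
  line <- which.max(rowSums(d^2))
  dl <- d[line, ]
  idx <- which(abs(dl) >= 0.01 * max(abs(dl)))
  rng <- idx[1]:idx[length(idx)]
  structure(
    list(samples = dl[rng], line = line, start_sample = rng[1],
         fs = frame_on$fs),
    class = "ae_template"
  )
}

#' Matched-filter correlation map of a frame against a template
#'
#' Normalized cross-correlation of every RF line with the template:
#' `corr[l, k] = sum(s[k..k+m-1] * T) / (||T|| * ||s[k..k+m-1]||)`.
#' The map maximum sits at the active-echo packet location when one is
#' present, and a template at the device's pulse frequency discriminates the
#' active echo from background echoes at the imaging frequency even at
#' equal amplitude.
#'
#' @param frame An `rf_frame`.
#' @param template An `ae_template` or a numeric waveform.
#' @return A matrix `lines x (n_samples - m + 1)` of class `corr_map` with
#'   attribute `template_length`.
#' @export
template_filter <- function(frame, template) {
  tpl <- if (inherits(template, "ae_template")) template$samples else template
  m <- length(tpl)
  n <- ncol(frame$samples)
  if (m > n) stop("template longer than a line", call. = FALSE)
  tnorm <- sqrt(sum(tpl^2))
  L <- nrow(frame$samples)
  out <- matrix(0, L, n - m + 1)
  if (tnorm == 0) return(structure(out, class = "corr_map", template_length = m))
  for (l in seq_len(L)) {
    s <- frame$samples[l, ]
    # sliding dot product via full convolution with the reversed template
    num <- stats::convolve(s, tpl, conj = TRUE, type = "open")[m:n]
    cs <- cumsum(c(0, s^2))
    en <- cs[(m + 1):(n + 1)] - cs[1:(n - m + 1)]
    den <- tnorm * sqrt(en)
    out[l, ] <- ifelse(den > tnorm * 1e-15, num / den, 0)
  }
  structure(out, class = "corr_map", template_length = m)
}

#' Signal- and contrast-to-noise ratio around the active-echo spot
#'
#' The differential signal is the echo-on image minus the echo-off image;
#' the background is the echo-off image; the surrounding area is a
#' `window x window` (default 50 x 50) pixel region around the spot centre.
#' The spot region is the set of pixels where the differential signal is at
#' least half its maximum. Then
#' `SNR = mean(DiffSignal over spot) / sd(background over window)` and
#' `CNR = |mean(on over spot) - mean(background over window)| /`
#' `sd(background over window)`.
#'
#' @param on,off Echo-on / echo-off images: `bmode_image`s (formed with a
#'   common normalization reference; see [snr_cnr_from_frames()]) or plain
#'   pixel matrices of identical shape.
#' @param spot_center Spot centre `c(line, sample)`; defaults to the
#'   differential-signal argmax.
#' @param window Side of the surrounding background window in pixels.
#' @return A list of class `metric_report` with `snr`, `cnr`, `spot_center`,
#'   `spot_size` (pixel count) and `window` bounds.
#' @export
compute_snr_cnr <- function(on, off, spot_center = NULL, window = 50) {
  P_on <- if (inherits(on, "bmode_image")) on$pixels else as.matrix(on)
  P_off <- if (inherits(off, "bmode_image")) off$pixels else as.matrix(off)
  if (!all(dim(P_on) == dim(P_off))) stop("images must have the same shape", call. = FALSE)
  d <- P_on - P_off
  dmax <- max(d)
  if (dmax <= 0) stop("no differential signal (echo-on equals echo-off)", call. = FALSE)
  if (is.null(spot_center)) {
    spot_center <- which(d == dmax, arr.ind = TRUE)[1, ]
  }
  half1 <- floor((window - 1) / 2)
  rows <- (spot_center[1] - half1):(spot_center[1] - half1 + window - 1)
  cols <- (spot_center[2] - half1):(spot_center[2] - half1 + window - 1)
  if (rows[1] < 1 || cols[1] < 1 || rows[window] > nrow(P_on) ||
      cols[window] > ncol(P_on)) {
    stop("the surrounding window does not fit inside the image", call. = FALSE)
  }
  spot <- d >= dmax / 2
  bg <- P_off[rows, cols]
  sd_bg <- stats::sd(bg)
  if (sd_bg == 0) stop("undefined metric: zero background standard deviation", call. = FALSE)
  structure(
    list(snr = mean(d[spot]) / sd_bg,
         cnr = abs(mean(P_on[spot]) - mean(bg)) / sd_bg,
         spot_center = unname(spot_center), spot_size = sum(spot),
         window = list(rows = range(rows), cols = range(cols))),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("SNR %.3f, CNR %.3f (spot of %d px at line %d, sample %d)\n",
              x$snr, x$cnr, x$spot_size, x$spot_center[1], x$spot_center[2]))
  invisible(x)
}

#' SNR/CNR directly from an echo-on / echo-off RF frame pair
#'
#' Forms both B-mode images with a shared normalization reference (the
#' larger of the two envelope maxima) so the on/off pixels are comparable,
#' then calls [compute_snr_cnr()].
#'
#' @param frame_on,frame_off `rf_frame`s.
#' @param dynamic_range_db Displayed dynamic range in dB.
#' @param window Surrounding-window side in pixels.
#' @param ref Optional shared normalization reference.
#' @return A `metric_report`.
#' @export
snr_cnr_from_frames <- function(frame_on, frame_off, dynamic_range_db = 50,
                                window = 50, ref = NULL) {
  env_max <- function(fr) max(abs(apply(fr$samples, 1, envelope)))
  if (is.null(ref)) ref <- max(env_max(frame_on), env_max(frame_off))
  on <- form_bmode(frame_on, dynamic_range_db, ref = ref)
  off <- form_bmode(frame_off, dynamic_range_db, ref = ref)
  compute_snr_cnr(on, off, window = window)
}

#' Elevational mid-plane sweep
#'
#' Emulates a translation-stage sweep: the probe is moved across elevational
#' offsets relative to the (fixed) element, and at each stage position the
#' trigger count and the peak received beacon amplitude are recorded, with
#' `repeats` re-measurements (re-seeded measurement noise per repeat). The
#' curves peak at the stage offset where the element crosses the mid-plane.
#' Offsets whose mean trigger count exceeds 40 are flagged `discarded` (the
#' spot is wide and distorted there) and excluded from derived fits.
#'
#' @param probe A [linear_probe()].
#' @param scn A [scene()].
#' @param device An [ae_device()]; its elevational position is overridden by
#'   the sweep offsets.
#' @param offsets_mm Sorted elevational offsets in millimetres.
#' @param repeats Measurements per offset.
#' @param seed Base seed for the measurement noise.
#' @param noise_sd Standard deviation of additive amplitude measurement
#'   noise (volts); 0 gives deterministic, exactly reproducible counts.
#' @param profile Optional [beam_profile()].
#' @return A `sweep_result`: a `data.frame` with `offset_mm`, `count_mean`,
#'   `count_sd`, `amp_mean`, `amp_sd`, `discarded`, plus attributes.
#' @export
midplane_sweep <- function(probe, scn, device, offsets_mm, repeats = 10,
                           seed = 1, noise_sd = 0, profile = NULL) {
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (is.unsorted(offsets_mm)) stop("offsets must be sorted", call. = FALSE)
  if (is.null(profile)) profile <- beam_profile(probe)
  counts <- matrix(0, repeats, length(offsets_mm))
  amps <- matrix(0, repeats, length(offsets_mm))
  for (r in seq_len(repeats)) {
    noise <- if (noise_sd > 0) {
      with_seed(seed + r, stats::rnorm(length(offsets_mm), 0, noise_sd))
    } else numeric(length(offsets_mm))
    for (j in seq_along(offsets_mm)) {
      # the stage moves the probe by `offset` along elevation, so the
      # element sits at (its own e) - offset relative to the mid-plane
      dev <- device
      dev$position[2] <- device$position[2] - offsets_mm[j] * 1e-3
      acq <- acquire_frame(probe, scn, dev, profile = profile,
                           compute_rf = FALSE)
      v <- if (acq$log$count > 0) max(acq$log$events$amplitude_v) else 0
      counts[r, j] <- acq$log$count
      amps[r, j] <- max(0, v + noise[j])
    }
  }
  res <- data.frame(
    offset_mm = offsets_mm,
    count_mean = colMeans(counts),
    count_sd = apply(counts, 2, stats::sd),
    amp_mean = colMeans(amps),
    amp_sd = apply(amps, 2, stats::sd)
  )
  res$discarded <- res$count_mean > 40
  structure(res, class = c("sweep_result", "data.frame"),
            repeats = repeats, seed = seed, noise_sd = noise_sd)
}

#' Localize the image mid-plane from a sweep
#'
#' Three estimators: `"count"` and `"amplitude"` return the argmax of the
#' respective mean curve with parabolic refinement over the three points
#' around the maximum; `"threshold"` returns the centre and half-width of
#' the offset interval where the amplitude stays at or above `q` times its
#' maximum (the operating band when the trigger level is set to
#' `q * max`). For a Gaussian elevational profile with sigma `s` the
#' threshold half-width is `s * sqrt(2 * log(1/q))` (0.459 s at `q = 0.9`).
#'
#' @param sweep A `sweep_result` (discarded offsets are ignored).
#' @param method `"count"`, `"amplitude"` or `"threshold"`.
#' @param q Amplitude fraction for the threshold method.
#' @return A list of class `midplane_estimate` with `estimate_mm`,
#'   `half_width_mm` (threshold method only) and `method`.
#' @export
localize_midplane <- function(sweep, method = c("count", "amplitude", "threshold"),
                              q = 0.9) {
  method <- match.arg(method)
  s <- sweep[!sweep$discarded, , drop = FALSE]
  x <- s$offset_mm
  y <- if (method == "count") s$count_mean else s$amp_mean
  if (length(unique(y)) <= 1) stop("flat sweep: no maximum to localize", call. = FALSE)
  if (method %in% c("count", "amplitude")) {
    # integer trigger counts plateau near the maximum: take the plateau
    # midpoint, refined parabolically when the maximum is a single point
    idx <- which(y == max(y))
    est <- mean(x[idx])
    i <- idx[1]
    if (length(idx) == 1 && i > 1 && i < length(y)) {
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      if (denom < 0) {
        delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
        est <- x[i] + delta * mean(diff(x[(i - 1):(i + 1)]))
      }
    }
    return(structure(list(estimate_mm = est, half_width_mm = NA_real_,
                          method = method), class = "midplane_estimate"))
  }
  level <- q * max(y)
  i <- which.max(y)
  cross <- function(idx_from, idx_to) {
    # linear interpolation of the crossing of `level` between grid points
    ii <- idx_from:idx_to
    below <- which(y[ii] < level)
    if (length(below) == 0) return(NA_real_)
    k <- if (idx_to > idx_from) ii[below[1]] else ii[below[1]]
    k_in <- k - sign(idx_to - idx_from) # last point at/above level
    x[k_in] + (level - y[k_in]) * (x[k] - x[k_in]) / (y[k] - y[k_in])
  }
  right <- if (i < length(y)) cross(i + 1, length(y)) else NA_real_
  left <- if (i > 1) cross(i - 1, 1) else NA_real_
  if (is.na(left) || is.na(right)) {
    stop("amplitude never falls below the threshold level inside the sweep",
         call. = FALSE)
  }
  structure(list(estimate_mm = (left + right) / 2,
                 half_width_mm = (right - left) / 2, method = method,
                 q = q), class = "midplane_estimate")
}

#' @export
print.midplane_estimate <- function(x, ...) {
  cat(sprintf("Mid-plane estimate (%s): %.3f mm", x$method, x$estimate_mm))
  if (!is.na(x$half_width_mm)) cat(sprintf(" (half-width %.3f mm)", x$half_width_mm))
  cat("\n")
  invisible(x)
}

#' Detectable range of the active echo from a sweep
#'
#' The largest elevational offset at which the device still triggers,
#' linearly interpolated to the first zero-count offset on each side. When
#' the counts never reach zero inside the sweep, a warning is raised and the
#' sweep extreme is returned.
#'
#' @param sweep A `sweep_result`.
#' @return Range in mm (0 for an all-zero sweep).
#' @export
detectable_range <- function(sweep) {
  x <- sweep$offset_mm
  y <- sweep$count_mean
  if (all(y == 0)) return(0)
  hit_extreme <- FALSE
  side <- function(ix) {
    # ix walks outward from the centre
    nz <- ix[which(y[ix] > 0)]
    k <- nz[length(nz)] # outermost non-zero
    pos <- which(ix == k)
    if (pos == length(ix)) {
      hit_extreme <<- TRUE
      return(abs(x[k]))
    }
    k1 <- ix[pos + 1] # first zero beyond
    abs(x[k] + y[k] * (x[k1] - x[k]) / (y[k] - y[k1]))
  }
  i0 <- which.min(abs(x))
  r_right <- if (any(y[i0:length(y)] > 0)) side(i0:length(x)) else 0
  r_left <- if (any(y[1:i0] > 0)) side(i0:1) else 0
  if (hit_extreme) {
    warning("counts never reach zero at the sweep extreme; returning the extreme",
            call. = FALSE)
  }
  max(r_left, r_right)
}

#' Trigger count over a grid of scanner settings
#'
#' Records the frame trigger count for every combination of transmit power,
#' transmit aperture, focus state and receiver gain, with the element fixed
#' in the scene. Cells with a count above 40 are marked `discarded`.
#'
#' @param probe Base [linear_probe()]; `tx_power`, `tx_aperture` and
#'   `focus_depth` are overridden per cell.
#' @param scn A [scene()].
#' @param device Base [ae_device()]; `rx_gain_db` is overridden per cell.
#' @param tx_powers,tx_apertures,gains_db Grid axes.
#' @param focus Logical vector of focus states (`TRUE` keeps the base
#'   probe's `focus_depth`, `FALSE` is unfocused).
#' @param elev_sigma Elevational beam sigma for the profile.
#' @return A `data.frame` with one row per cell: `tx_power`, `tx_aperture`,
#'   `focused`, `gain_db`, `count`, `discarded`.
#' @export
parameter_grid <- function(probe, scn, device, tx_powers, tx_apertures,
                           focus = c(TRUE, FALSE), gains_db,
                           elev_sigma = 3e-3) {
  grid <- expand.grid(tx_power = tx_powers, tx_aperture = tx_apertures,
                      focused = focus, gain_db = gains_db)
  grid$count <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    p <- probe
    p$tx_power <- grid$tx_power[i]
    p$tx_aperture <- grid$tx_aperture[i]
    if (!grid$focused[i]) p$focus_depth <- NA_real_
    dev <- device
    dev$rx_gain_db <- grid$gain_db[i]
    prof <- beam_profile(p, elev_sigma = elev_sigma)
    acq <- acquire_frame(p, scn, dev, profile = prof, compute_rf = FALSE)
    grid$count[i] <- acq$log$count
  }
  grid$discarded <- grid$count > 40
  grid
}
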