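# Shared small-scale simulation setups for the test suite.

water_scene <- function(c = 1480) scene(medium(c = c, assumed_c = c))

# A compact probe: 64 lines, 40 MHz sampling, 5 cm depth.
small_probe <- function(...) {
  args <- utils::modifyList(list(lines_per_frame = 64, fs = 40e6), list(...))
  do.call(linear_probe, args)
}

# Device parked on the mid-plane at 40 mm, on the line-32 axis.
small_device <- function(probe = small_probe(), ...) {
  lx <- line_schedule(probe)$line_x
  ae_device(position = c(lx[32], 0, 0.04), ...)
}

axial_sample_m <- function(probe, med) med$assumed_c / (2 * probe$fs)

# Envelope argmax of a frame as (line, sample).
frame_argmax <- function(frame) {
  env <- t(apply(frame$samples, 1, envelope))
  which(env == max(env), arr.ind = TRUE)[1, ]
}

# Brute-force first-crossing comparator used as the oracle for
# trigger_decision().
first_crossing_oracle <- function(trace, threshold) {
  for (i in seq_along(trace)) if (abs(trace[i]) >= threshold) return(i)
  NULL
}
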