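test_that("line schedule spans the array uniformly with one line per period", {
  pr <- linear_probe(n_elements = 16, pitch = 0.3e-3, lines_per_frame = 16,
                     tx_aperture = 8, line_period = 125e-6, max_depth = 0.04)
  s <- line_schedule(pr)
  expect_equal(nrow(s), 16)
  expect_equal(unique(round(diff(s$line_x), 12)), 0.3e-3)
  expect_equal(s$t_start[1], 0)
  expect_true(all(diff(s$line_x) > 0))

  pr2 <- linear_probe(lines_per_frame = 256, line_period = 200e-6)
  expect_equal(max(line_schedule(pr2)$t_start), 255 * 200e-6)
})

test_that("beam amplitude is Gaussian in lateral and elevational offset", {
  pr <- small_probe()
  prof <- beam_profile(pr)
  z <- 0.04
  peak <- beam_amplitude(pr, prof, 0, c(0, 0, z))
  expect_equal(peak, peak_amplitude(prof, z), tolerance = 1e-12)

  sx <- lateral_sigma(prof, z)
  expect_equal(beam_amplitude(pr, prof, 0, c(sx, 0, z)) / peak,
               exp(-1 / 2), tolerance = 1e-12)
  expect_equal(beam_amplitude(pr, prof, 0, c(0, 2e-3, z)),
               beam_amplitude(pr, prof, 0, c(0, -2e-3, z)), tolerance = 1e-15)
  expect_error(beam_amplitude(pr, prof, 0, c(0, 0, -0.01)), "z > 0")

  # focused profile has its waist at the focus; unfocused is constant
  zf <- pr$focus_depth
  expect_lt(lateral_sigma(prof, zf), lateral_sigma(prof, zf + 0.02))
  unf <- beam_profile(linear_probe(focus_depth = NA))
  expect_equal(lateral_sigma(unf, 0.01), lateral_sigma(unf, 0.05))
})

test_that("RF lines place echoes at round-trip times and AE packets at firing times", {
  pr <- small_probe()
  med <- medium(c = 1540, assumed_c = 1540)
  prof <- beam_profile(pr)

  expect_equal(synthesize_rf_line(pr, scene(med), 0, list(), prof),
               numeric(n_rf_samples(pr, med)))

  # single on-axis scatterer at 30 mm
  field <- structure(list(
    positions = matrix(c(0, 0, 0.03), 1, 3,
                       dimnames = list(NULL, c("x", "e", "z"))),
    reflectivities = 1, seed = 0, spec = NULL
  ), class = "scatterer_field")
  line <- synthesize_rf_line(pr, scene(med, field), 0, list(), prof)
  env <- envelope(line)
  expect_equal(which.max(env), round(2 * 0.03 / 1540 * pr$fs) + 1)

  # one AE firing in an empty scene
  dev <- ae_device(position = c(0, 0, 0.04), loop_delay = 0)
  ev <- structure(list(sample = NA, t_trigger = 10e-6, amplitude_v = 1),
                  class = "trigger_event")
  fr <- make_firing(ev, dev, pr$fs)
  line2 <- synthesize_rf_line(pr, scene(med), 0, list(fr), prof,
                              element_pos = dev$position)
  t_expect <- 10e-6 + 0.04 / 1540
  expect_equal(which.max(envelope(line2)), round(t_expect * pr$fs) + 1)

  bad <- fr; bad$fire_time <- pr$line_period + 1e-6
  expect_error(synthesize_rf_line(pr, scene(med), 0, list(bad), prof,
                                  element_pos = dev$position), "line window")
})

test_that("acquisition is linear: on-frame minus off-frame equals the AE-only frame", {
  pr <- small_probe()
  med <- medium(c = 1480, assumed_c = 1480)
  phant <- make_phantom(phantom_spec(c(-10e-3, 10e-3), c(-3e-3, 3e-3),
                                     c(10e-3, 45e-3), density = 20), 3)
  sc <- scene(med, phant)
  dev_on <- small_device(pr)
  dev_off <- dev_on; dev_off$mode <- "off"

  on <- acquire_frame(pr, sc, dev_on)
  off <- acquire_frame(pr, sc, dev_off)
  ae_only <- acquire_frame(pr, scene(med), dev_on)

  expect_gt(max(abs(ae_only$frame$samples)), 0)
  expect_equal(on$frame$samples - off$frame$samples, ae_only$frame$samples,
               tolerance = 1e-9)
})

test_that("gating and threshold contracts hold in the event loop", {
  pr <- small_probe()
  sc <- water_scene()
  dev <- small_device(pr)

  # blink gate off: triggers may log but nothing fires
  dev_gated <- dev
  dev_gated$blink_duty <- 0.5
  acq <- acquire_frame(pr, sc, dev_gated, frame_start = 0.3) # in the off half
  expect_gt(acq$log$count, 0)
  expect_true(all(vapply(acq$firings, length, integer(1)) == 0))
  no_dev <- acquire_frame(pr, sc, NULL)
  expect_equal(acq$frame$samples, no_dev$frame$samples)

  # threshold above all beacon amplitudes: no triggers, no firings
  deaf <- dev; deaf$threshold <- 1e9
  acq2 <- acquire_frame(pr, sc, deaf)
  expect_equal(acq2$log$count, 0)
  expect_true(all(vapply(acq2$firings, length, integer(1)) == 0))

  # triggered line carries the AE packet loop_delay after the passive echo time
  acq3 <- acquire_frame(pr, sc, dev)
  expect_gt(acq3$log$count, 0)
  lmax <- frame_argmax(acq3$frame)
  t_spot <- unname(lmax[2] - 1) / pr$fs
  expect_lt(abs(t_spot - (2 * 0.04 / 1480 + dev$loop_delay)), 1.5 / pr$fs)

  # trigger timestamps equal beacon arrival; echo fire times add loop_delay
  ev <- acq3$log$events
  d <- sqrt((dev$position[1] - line_schedule(pr)$line_x[ev$line])^2 + 0.04^2)
  expect_equal(ev$t_trigger, d / 1480, tolerance = 1e-12)
})

test_that("trigger count is elevation-symmetric and grows with aperture and gain", {
  pr <- small_probe()
  sc <- water_scene()
  count_at <- function(e_mm, probe = pr, gain = 19, aperture = probe$tx_aperture) {
    p <- probe; p$tx_aperture <- aperture
    dev <- ae_device(position = c(0, e_mm * 1e-3, 0.04), rx_gain_db = gain)
    acquire_frame(p, sc, dev, profile = beam_profile(p),
                  compute_rf = FALSE)$log$count
  }
  offs <- seq(-6, 6, by = 1.5)
  counts <- vapply(offs, count_at, numeric(1))
  expect_equal(counts, rev(counts)) # even symmetry
  expect_equal(counts[offs == 0], max(counts))
  half <- counts[offs >= 0]
  expect_true(all(diff(half) <= 0)) # non-increasing in |e|

  # aperture ordering, with the element near (not exactly at) the focus
  pr_near <- small_probe(focus_depth = 0.034)
  expect_gte(count_at(0, probe = pr_near, aperture = 64),
             count_at(0, probe = pr_near, aperture = 32))
  expect_gte(count_at(0, gain = 25), count_at(0, gain = 19))
})

test_that("focused acquisition is less gain-sensitive than unfocused", {
  sc <- water_scene()
  count <- function(focused, gain) {
    p <- linear_probe(lines_per_frame = 64, fs = 40e6,
                      focus_depth = if (focused) 0.034 else NA)
    dev <- ae_device(position = c(0, 0, 0.04), rx_gain_db = gain)
    acquire_frame(p, sc, dev, profile = beam_profile(p),
                  compute_rf = FALSE)$log$count
  }
  d_focused <- count(TRUE, 25) - count(TRUE, 15)
  d_unfocused <- count(FALSE, 25) - count(FALSE, 15)
  expect_lt(d_focused, d_unfocused)
})
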