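test_that("frame subtraction recovers the active-echo waveform", {
  pr <- small_probe()
  med <- medium(c = 1480, assumed_c = 1480)
  phant <- make_phantom(phantom_spec(c(-10e-3, 10e-3), c(-3e-3, 3e-3),
                                     c(10e-3, 45e-3), density = 15), 9)
  sc <- scene(med, phant)
  dev <- small_device(pr)
  dev_off <- dev; dev_off$mode <- "off"

  on <- acquire_frame(pr, sc, dev)$frame
  off <- acquire_frame(pr, sc, dev_off)$frame
  tpl <- acquire_template(on, off)

  # equals the AE-only contribution on the same support (superposition)
  ae_only <- acquire_frame(pr, scene(med), dev)$frame
  ref <- ae_only$samples[tpl$line,
                         tpl$start_sample + seq_along(tpl$samples) - 1]
  expect_equal(tpl$samples, ref, tolerance = 1e-9)

  # support length is of the order of the pulse duration (band-limited tails)
  dur_samples <- dev$pulse_cycles / dev$pulse_freq * pr$fs
  expect_gt(length(tpl$samples), dur_samples)
  expect_lt(length(tpl$samples), 12 * dur_samples)

  expect_error(acquire_template(on, on), "identical")
})

test_that("template filtering equals brute-force normalized correlation", {
  pr <- small_probe(lines_per_frame = 4, max_depth = 0.02)
  med <- medium(c = 1480, assumed_c = 1480)
  tpl <- gabor_pulse(pr$fs, 9e6, 2)$samples
  n <- n_rf_samples(pr, med)
  set.seed(21)
  samples <- matrix(stats::rnorm(4 * n, sd = 0.1), 4, n)
  frame <- structure(list(samples = samples, fs = pr$fs,
                          line_x = 1:4, frame_start = 0, assumed_c = 1480,
                          line_period = pr$line_period), class = "rf_frame")
  cm <- template_filter(frame, tpl)
  m <- length(tpl)
  tnorm <- sqrt(sum(tpl^2))
  for (l in 1:4) {
    brute <- vapply(seq_len(n - m + 1), function(k) {
      w <- samples[l, k:(k + m - 1)]
      sum(w * tpl) / (tnorm * sqrt(sum(w^2)))
    }, numeric(1))
    expect_equal(unname(cm[l, ]), brute, tolerance = 1e-9)
  }
  zero_frame <- frame; zero_frame$samples <- matrix(0, 4, n)
  expect_equal(max(abs(template_filter(zero_frame, tpl))), 0)
})

test_that("matched filtering finds the packet and discriminates frequency", {
  fs <- 40e6
  tpl <- gabor_pulse(fs, 9e6, 4)$samples
  n <- 2048
  set.seed(31)
  hits <- 0
  for (i in 1:25) {
    k <- sample(200:(n - 200), 1)
    line <- numeric(n)
    line[k + seq_along(tpl) - length(tpl) %/% 2 - 1] <- tpl
    frame <- structure(list(samples = rbind(line), fs = fs, line_x = 0,
                            frame_start = 0, assumed_c = 1540,
                            line_period = 1), class = "rf_frame")
    cm <- template_filter(frame, tpl)
    k_hat <- which.max(cm[1, ]) + length(tpl) %/% 2
    if (abs(k_hat - k) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 24)

  # 9 MHz template vs a 10 MHz interferer at equal amplitude
  ae <- gabor_pulse(fs, 9e6, 4)$samples
  bg <- gabor_pulse(fs, 10e6, 4)$samples
  line <- numeric(n)
  line[400 + seq_along(ae)] <- ae
  line[1200 + seq_along(bg)] <- line[1200 + seq_along(bg)] + bg
  frame <- structure(list(samples = rbind(line), fs = fs, line_x = 0,
                          frame_start = 0, assumed_c = 1540,
                          line_period = 1), class = "rf_frame")
  cm <- template_filter(frame, ae)[1, ]
  peak_ae <- max(cm[300:700])
  peak_bg <- max(cm[1100:1500])
  expect_gt(peak_ae, peak_bg)
})

test_that("SNR and CNR match hand-computed values on constructed images", {
  # background: checkerboard +/-2 around mean 10 -> mean 10, known sd
  off <- matrix(10 + 2 * (-1)^(outer(1:60, 1:60, `+`)), 60, 60)
  on <- off
  spot <- as.matrix(expand.grid(29:32, 29:32))
  on[spot] <- on[spot] + 10
  mr <- compute_snr_cnr(on, off, spot_center = c(30, 30), window = 50)

  d <- on - off
  spot_mask <- d >= max(d) / 2
  rows <- 6:55; cols <- 6:55 # the 50x50 window centred at (30, 30)
  sd_bg <- stats::sd(off[rows, cols])
  expect_equal(mr$snr, mean(d[spot_mask]) / sd_bg, tolerance = 1e-9)
  expect_equal(mr$cnr, abs(mean(on[spot_mask]) - mean(off[rows, cols])) / sd_bg,
               tolerance = 1e-9)
  expect_equal(mr$spot_size, 16)

  # uniform +10 spot over zero-mean background with sd exactly 2
  expect_equal(mr$snr, 10 / sd_bg, tolerance = 1e-9)

  expect_error(compute_snr_cnr(off, off), "no differential")
  flat <- matrix(1, 60, 60)
  expect_error(compute_snr_cnr(flat + diag(60) * 5, flat, window = 50),
               "window|standard deviation")
  expect_error(compute_snr_cnr(on, off, spot_center = c(3, 3), window = 50),
               "window")

  # doubling the added spot intensity never decreases the SNR
  on2 <- off; on2[spot] <- on2[spot] + 20
  mr2 <- compute_snr_cnr(on2, off, spot_center = c(30, 30), window = 50)
  expect_gte(mr2$snr, mr$snr)
})

test_that("the elevational sweep is symmetric, peaked at zero and reproducible", {
  pr <- small_probe()
  sc <- water_scene()
  dev <- ae_device(position = c(0, 0, 0.04))
  offs <- seq(-9, 9, by = 1)
  sw <- midplane_sweep(pr, sc, dev, offs, repeats = 2, seed = 4)
  expect_equal(sw$count_mean, rev(sw$count_mean))
  expect_equal(sw$count_mean[offs == 0], max(sw$count_mean))
  expect_true(all(diff(sw$count_mean[offs >= 0]) <= 0))
  expect_true(all(sw$count_sd == 0)) # noiseless: deterministic

  sw2 <- midplane_sweep(pr, sc, dev, offs, repeats = 2, seed = 4)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))

  # beyond beam support the count is zero
  far <- midplane_sweep(pr, sc, dev, c(30, 40), repeats = 1, seed = 1)
  expect_equal(far$count_mean, c(0, 0))
})

test_that("mid-plane localization is exact for symmetric sweeps and recovers sigma", {
  pr <- small_probe()
  sc <- water_scene()
  dev <- ae_device(position = c(0, 0, 0.04))
  offs <- seq(-9, 9, by = 0.25)

  for (sig_mm in c(1.5, 2, 3)) {
    prof <- beam_profile(pr, elev_sigma = sig_mm * 1e-3)
    sw <- midplane_sweep(pr, sc, dev, offs, repeats = 1, seed = 1,
                         profile = prof)
    est <- localize_midplane(sw, "count")
    expect_equal(est$estimate_mm, 0)
    amp <- localize_midplane(sw, "amplitude")
    expect_equal(amp$estimate_mm, 0)
    thr <- localize_midplane(sw, "threshold", q = 0.9)
    # Gaussian profile: half-width = sigma * sqrt(2 ln(1/0.9)) = 0.459 sigma
    expect_equal(thr$half_width_mm, sig_mm * sqrt(2 * log(1 / 0.9)),
                 tolerance = 0.02)
  }

  flat <- midplane_sweep(pr, sc, dev, c(30, 35, 40), repeats = 1, seed = 1)
  expect_error(localize_midplane(flat, "count"), "flat")

  # off-centre element is recovered within the grid spacing
  dev2 <- ae_device(position = c(0, 1.6e-3, 0.04))
  sw2 <- midplane_sweep(pr, sc, dev2, offs, repeats = 1, seed = 1)
  est2 <- localize_midplane(sw2, "amplitude")
  expect_lt(abs(est2$estimate_mm - 1.6), 0.25)
})

test_that("detectable range interpolates to the first zero and grows with gain", {
  sw <- structure(
    data.frame(offset_mm = -3:3,
               count_mean = c(0, 2, 7, 12, 7, 2, 0),
               count_sd = 0, amp_mean = c(0, 2, 7, 12, 7, 2, 0), amp_sd = 0,
               discarded = FALSE),
    class = c("sweep_result", "data.frame"))
  expect_equal(detectable_range(sw), 3)

  sw0 <- sw; sw0$count_mean <- rep(0, 7)
  expect_equal(detectable_range(sw0), 0)

  swx <- sw; swx$count_mean <- c(1, 2, 7, 12, 7, 2, 1)
  expect_warning(r <- detectable_range(swx), "extreme")
  expect_equal(r, 3)

  pr <- small_probe()
  sc <- water_scene()
  offs <- seq(-14, 14, by = 1)
  range_at <- function(gain) {
    dev <- ae_device(position = c(0, 0, 0.04), rx_gain_db = gain)
    detectable_range(midplane_sweep(pr, sc, dev, offs, repeats = 1, seed = 1))
  }
  expect_gte(range_at(25), range_at(15))
})

test_that("the parameter grid reproduces the qualitative orderings", {
  pr <- small_probe(focus_depth = 0.034)
  sc <- water_scene()
  dev <- ae_device(position = c(0, 0, 0.04))
  tab <- parameter_grid(pr, sc, dev, tx_powers = c(0, 1),
                        tx_apertures = c(32, 64), focus = c(TRUE, FALSE),
                        gains_db = c(15, 25))
  # zero transmit power: no triggers anywhere
  expect_true(all(tab$count[tab$tx_power == 0] == 0))
  # larger aperture never lowers the count at matched settings
  for (g in c(15, 25)) for (f in c(TRUE, FALSE)) {
    c32 <- tab$count[tab$tx_power == 1 & tab$tx_aperture == 32 &
                       tab$focused == f & tab$gain_db == g]
    c64 <- tab$count[tab$tx_power == 1 & tab$tx_aperture == 64 &
                       tab$focused == f & tab$gain_db == g]
    expect_gte(c64, c32)
  }
  # focused counts move less per dB of gain than unfocused
  slope <- function(f) {
    cc <- tab$count[tab$tx_power == 1 & tab$tx_aperture == 32 & tab$focused == f]
    abs(diff(cc))
  }
  expect_lt(slope(TRUE), slope(FALSE))
  expect_true(all(tab$discarded == (tab$count > 40)))
})
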