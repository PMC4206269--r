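test_that("pixel fire time follows t = 2y/c - d/c", {
  expect_equal(pixel_fire_time(0.04, d = 0.05, c = 1540), 0.03 / 1540,
               tolerance = 1e-12) # 19.48 us
  expect_equal(pixel_fire_time(0.025, d = 0.05, c = 1540), 0) # d = 2y boundary
  expect_error(pixel_fire_time(0.02, d = 0.05, c = 1540), "unreachable")

  # strictly increasing in y, strictly decreasing in d
  y <- seq(0.03, 0.05, by = 1e-3)
  expect_true(all(diff(pixel_fire_time(y, d = 0.05, c = 1540)) > 0))
  d <- seq(0.02, 0.05, by = 1e-3)
  t_d <- vapply(d, function(di) pixel_fire_time(0.04, d = di, c = 1540),
                numeric(1))
  expect_true(all(diff(t_d) < 0))

  # geometric d from element position and line
  t_geo <- pixel_fire_time(0.04, c = 1540, element_pos = c(3e-3, 0, 0.04),
                           line_x = 0)
  d_geo <- sqrt(3e-3^2 + 0.04^2)
  expect_equal(t_geo, (2 * 0.04 - d_geo) / 1540, tolerance = 1e-15)
})

test_that("frame-synchronized rasterization maps pixels to ordered firings", {
  pr <- small_probe()
  elem <- c(0, 0, 0.04)
  bar <- pattern_spec(data.frame(line = 32, depth = c(30e-3, 35e-3, 40e-3),
                                 intensity = 1), "absolute")
  plan <- rasterize_sync(bar, pr, elem, c = 1480)
  expect_equal(nrow(plan$firings), 3)
  expect_true(all(diff(plan$firings$t) > 0)) # monotone in depth
  expect_equal(plan$method, "sync")

  empty <- pattern_spec(data.frame(line = integer(0), depth = numeric(0),
                                   intensity = numeric(0)), "absolute")
  expect_equal(nrow(rasterize_sync(empty, pr, elem)$firings), 0)

  # unreachable pixels are skipped with a warning, not an abort
  shallow <- pattern_spec(data.frame(line = 32, depth = c(1e-3, 30e-3),
                                     intensity = 1), "absolute")
  expect_warning(plan2 <- rasterize_sync(shallow, pr, elem, c = 1480),
                 "skipped")
  expect_equal(nrow(plan2$firings), 1)
  expect_equal(nrow(plan2$skipped), 1)

  # firings closer than min_gap on one line merge with summed intensity
  close_px <- pattern_spec(data.frame(line = 10, depth = c(30e-3, 30.01e-3),
                                      intensity = 0.4), "absolute")
  merged <- rasterize_sync(close_px, pr, elem, c = 1480, min_gap = 1e-6)
  expect_equal(nrow(merged$firings), 1)
  expect_equal(merged$firings$amplitude, 0.8)
})

test_that("line-period estimation divides differences by integer line gaps", {
  expect_equal(estimate_line_period(c(100, 225, 350) * 1e-6), 125e-6)
  # non-adjacent triggers snap to integer multiples of the base period
  expect_equal(estimate_line_period(c(100, 225, 350, 600) * 1e-6), 125e-6)
  expect_equal(estimate_line_period(c(100, 350) * 1e-6, base_period = 125e-6),
               125e-6)
  expect_error(estimate_line_period(c(100e-6)), "at least two")

  # exact recovery from a trigger train with skipped lines
  period <- 150e-6
  times <- c(0, 1, 2, 3, 5, 8, 9, 13) * period
  expect_equal(estimate_line_period(times), period, tolerance = 1e-15)
})

test_that("element-relative rasterization fires at beacon-referenced delays", {
  pr <- small_probe(line_period = 125e-6)
  ref <- list(line = 20, t_trigger = 0.04 / 1540)
  px <- pattern_spec(data.frame(dline = c(0, 2), ddepth = c(0, 5e-3),
                                intensity = 1), "element_relative")
  plan <- rasterize_relative(px, 125e-6, ref, pr, c = 1540)
  expect_equal(plan$firings$line, c(20, 22))
  # (0,0) pixel fires at the beacon arrival itself
  expect_equal(plan$firings$t[1], ref$t_trigger, tolerance = 1e-15)
  # (+2 lines, +5 mm): 2 periods (across lines) + 6.49 us within the line
  expect_equal(plan$firings$t[2] - plan$firings$t[1], 2 * 5e-3 / 1540,
               tolerance = 1e-12)
  # realized absolute delay from the reference trigger
  abs_delay <- (plan$firings$line[2] - ref$line) * 125e-6 +
    (plan$firings$t[2] - ref$t_trigger)
  expect_equal(abs_delay, 250e-6 + 2 * 5e-3 / 1540, tolerance = 1e-12)

  # pixels pushed outside the frame are skipped and logged
  far <- pattern_spec(data.frame(dline = 100, ddepth = 0, intensity = 1),
                      "element_relative")
  expect_warning(plan2 <- rasterize_relative(far, 125e-6, ref, pr), "skipped")
  expect_equal(nrow(plan2$firings), 0)
  expect_equal(nrow(plan2$skipped), 1)
})

test_that("mid-plane bars scale with the trigger count by ceiling division", {
  expect_equal(nrow(midplane_bars(0)$pixels), 0)
  n_bars <- function(count) {
    px <- midplane_bars(count, counts_per_bar = 5)$pixels
    if (nrow(px) == 0) 0 else length(unique(px$ddepth))
  }
  expect_equal(n_bars(12), 3)
  expect_equal(n_bars(13), 3)
  expect_equal(n_bars(16), 4)
  counts <- 0:30
  expect_true(all(diff(vapply(counts, n_bars, numeric(1))) >= 0))
})

test_that("an injected pattern moves with the element (relative anchoring)", {
  pr <- small_probe()
  med <- medium(c = 1480, assumed_c = 1480)
  sc <- scene(med)
  sched <- line_schedule(pr)
  px <- pattern_spec(data.frame(dline = c(-2, 0, 2), ddepth = 4e-3,
                                intensity = 1), "element_relative")

  spot_lines <- function(ref_line) {
    pos <- c(sched$line_x[ref_line], 0, 0.04)
    dev <- ae_device(position = pos, mode = "pattern")
    d0 <- sqrt(sum((pos - c(sched$line_x[ref_line], 0, 0))^2))
    plan <- rasterize_relative(px, pr$line_period,
                               list(line = ref_line, t_trigger = d0 / 1480),
                               pr, c = 1480)
    acq <- acquire_frame(pr, sc, dev, plan = plan)
    env <- t(apply(acq$frame$samples, 1, envelope))
    sort(unique(which(env > 0.5 * max(env), arr.ind = TRUE)[, 1]))
  }
  l1 <- spot_lines(30)
  l2 <- spot_lines(31)
  expect_equal(l2, l1 + 1)
})
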