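#' Load a scenario configuration file
#'
#' A scenario is a YAML file describing one self-contained experiment:
#' probe (preset plus overrides), medium, phantom, device, optional pattern,
#' and an experiment block. Numeric values may carry unit suffixes
#' (`"40 mm"`, `"200 us"`, `"10 MHz"`); everything is normalized to SI on
#' load. Unknown top-level keys are an error, as is a missing seed when the
#' scenario has any stochastic element (a phantom with positive density or
#' sweep measurement noise).
#'
#' @param path Path to the YAML scenario file.
#' @return A fully resolved object of class `scenario` with elements
#'   `probe`, `medium`, `phantom` (a [phantom_spec()] or `NULL`), `device`,
#'   `pattern`, `experiment`, `elev_sigma` and `seed`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("probe", "medium", "phantom", "device", "pattern", "experiment",
             "seed", "elev_sigma")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }

  pq <- function(block, key, default = NULL) {
    v <- block[[key]]
    if (is.null(v)) return(default)
    parse_quantity(unlist(v), key)
  }

  pr <- raw$probe %||% list()
  probe_args <- list(
    n_elements = pq(pr, "n_elements"), pitch = pq(pr, "pitch"),
    f0_tx = pq(pr, "f0_tx"), fs = pq(pr, "fs"),
    lines_per_frame = pq(pr, "lines_per_frame"),
    tx_aperture = pq(pr, "tx_aperture"),
    tx_power = pq(pr, "tx_power"), line_period = pq(pr, "line_period"),
    max_depth = pq(pr, "max_depth"), tx_cycles = pq(pr, "tx_cycles"),
    frame_rate = pq(pr, "frame_rate"), mode = pr$mode
  )
  if (!is.null(pr$rx_band)) probe_args$rx_band <- parse_quantity(unlist(pr$rx_band), "rx_band")
  if (!is.null(pr$focus_depth)) {
    probe_args$focus_depth <- if (identical(pr$focus_depth, "none")) NA_real_
                              else parse_quantity(pr$focus_depth, "focus_depth")
  }
  probe <- do.call(linear_probe, probe_args[!vapply(probe_args, is.null, logical(1))])

  md <- raw$medium %||% list()
  med <- if (!is.null(md$layers)) {
    layers <- do.call(rbind, lapply(md$layers, function(l) data.frame(
      thickness = parse_quantity(l$thickness %||% Inf, "thickness"),
      c = parse_quantity(l$c, "c"),
      attenuation = parse_quantity(l$attenuation %||% 0, "attenuation")
    )))
    medium(layers = layers, assumed_c = pq(md, "assumed_c"))
  } else {
    medium(c = pq(md, "c", 1540), attenuation = pq(md, "attenuation", 0),
           assumed_c = pq(md, "assumed_c"))
  }

  ph <- raw$phantom
  phantom <- NULL
  if (!is.null(ph)) {
    phantom <- phantom_spec(
      x_range = pq(ph, "x_range", c(-20e-3, 20e-3)),
      e_range = pq(ph, "e_range", c(-5e-3, 5e-3)),
      z_range = pq(ph, "z_range", c(5e-3, probe$max_depth)),
      density = pq(ph, "density", 50),
      reflectivity = ph$reflectivity %||% list(family = "rayleigh", scale = 1),
      inclusions = lapply(ph$inclusions %||% list(), function(inc) list(
        center = parse_quantity(unlist(inc$center), "center"),
        radius = parse_quantity(inc$radius, "radius"),
        amplitude = parse_quantity(inc$amplitude, "amplitude")
      ))
    )
  }

  dv <- raw$device %||% list()
  device_args <- list(
    position = pq(dv, "position"), orientation = pq(dv, "orientation"),
    rx_gain_db = pq(dv, "rx_gain_db"), threshold = pq(dv, "threshold"),
    loop_delay = pq(dv, "loop_delay"), pulse_freq = pq(dv, "pulse_freq"),
    pulse_cycles = pq(dv, "pulse_cycles"),
    drive_voltage = pq(dv, "drive_voltage"),
    blink_period = pq(dv, "blink_period"), blink_duty = pq(dv, "blink_duty"),
    mode = dv$mode, sensitivity = pq(dv, "sensitivity")
  )
  device <- do.call(ae_device, device_args[!vapply(device_args, is.null, logical(1))])

  pattern <- NULL
  pt <- raw$pattern
  if (!is.null(pt)) {
    if (!is.null(pt$bitmap)) {
      pattern <- pattern_from_bitmap(
        unlist(pt$bitmap),
        line0 = pq(pt, "line0", 1), depth0 = pq(pt, "depth0", 20e-3),
        dline = pq(pt, "dline", 1), ddepth = pq(pt, "ddepth", 1e-3)
      )
    } else if (!is.null(pt$pixels)) {
      px <- do.call(rbind, lapply(pt$pixels, function(p) as.data.frame(
        lapply(p, parse_quantity)
      )))
      pattern <- pattern_spec(px, anchor = pt$anchor %||% "absolute")
    }
  }

  exper <- raw$experiment %||% list(type = "single-frame")
  exper$type <- exper$type %||% "single-frame"
  seed <- raw$seed
  stochastic <- (!is.null(phantom) && phantom$density > 0) ||
    (pq(exper, "noise_sd", 0) > 0)
  if (stochastic && is.null(seed)) {
    stop("a seed is required for a scenario with stochastic elements", call. = FALSE)
  }

  structure(
    list(probe = probe, medium = med, phantom = phantom, device = device,
         pattern = pattern, experiment = exper,
         elev_sigma = pq(raw, "elev_sigma", 3e-3), seed = seed %||% 1L),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", x$experiment$type, "(seed", x$seed, ")\n")
  print(x$probe)
  print(x$device)
  invisible(x)
}

#' Write a resolved scenario back to YAML
#'
#' Dumps a loaded scenario in fully resolved SI units; loading the dump
#' yields an identical scenario (round-trip stability).
#'
#' @param scn A `scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  p <- scn$probe
  out <- list(
    probe = list(
      n_elements = p$n_elements, pitch = p$pitch, f0_tx = p$f0_tx,
      rx_band = p$rx_band, fs = p$fs, lines_per_frame = p$lines_per_frame,
      tx_aperture = p$tx_aperture,
      focus_depth = if (is.na(p$focus_depth)) "none" else p$focus_depth,
      tx_power = p$tx_power, line_period = p$line_period,
      max_depth = p$max_depth, tx_cycles = p$tx_cycles, mode = p$mode
    ),
    medium = list(
      layers = lapply(seq_len(nrow(scn$medium$layers)), function(i) list(
        thickness = scn$medium$layers$thickness[i],
        c = scn$medium$layers$c[i],
        attenuation = scn$medium$layers$attenuation[i]
      )),
      assumed_c = scn$medium$assumed_c
    ),
    device = {
      d <- scn$device
      list(position = d$position, orientation = d$orientation,
           rx_gain_db = d$rx_gain_db, threshold = d$threshold,
           loop_delay = d$loop_delay, pulse_freq = d$pulse_freq,
           pulse_cycles = d$pulse_cycles, drive_voltage = d$drive_voltage,
           blink_period = d$blink_period, blink_duty = d$blink_duty,
           mode = d$mode, sensitivity = d$sensitivity)
    },
    experiment = scn$experiment,
    elev_sigma = scn$elev_sigma,
    seed = scn$seed
  )
  if (!is.null(scn$phantom)) {
    ph <- scn$phantom
    out$phantom <- list(x_range = ph$x_range, e_range = ph$e_range,
                        z_range = ph$z_range, density = ph$density,
                        reflectivity = ph$reflectivity)
  }
  if (!is.null(scn$pattern)) {
    out$pattern <- list(anchor = scn$pattern$anchor,
                        pixels = lapply(seq_len(nrow(scn$pattern$pixels)),
                                        function(i) as.list(scn$pattern$pixels[i, ])))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

write_manifest <- function(files, out_dir) {
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest
}

write_trigger_csv <- function(log, path, frame = log$frame_index) {
  ev <- log$events
  df <- if (nrow(ev) == 0) {
    data.frame(frame = integer(0), line = integer(0), time_us = numeric(0),
               amplitude = numeric(0))
  } else {
    data.frame(frame = frame, line = ev$line, time_us = ev$t_trigger * 1e6,
               amplitude = ev$amplitude_v)
  }
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run a scenario and write its artifacts
#'
#' Executes the scenario's experiment and writes deterministic artifacts
#' (CSV tables, plain-PGM images, JSON sidecars) plus a `manifest.json`
#' listing every file with its MD5 hash; the same scenario and seed always
#' produce a hash-identical manifest.
#'
#' Experiment types: `single-frame` (one acquisition; trigger log, B-mode),
#' `sweep` (elevational mid-plane sweep; table plus localization summary),
#' `grid` (parameter grid table), `mmode` (frame sequence at the device
#' line; M-mode image), `inject` (pattern injection; plan and B-mode), and
#' `modes` (SNR/CNR across the four imaging modes).
#'
#' @param scn A `scenario` from [load_scenario()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest `data.frame`, invisibly.
#' @export
run_scenario <- function(scn, out_dir) {
  stopifnot(inherits(scn, "scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- scn$probe
  med <- scn$medium
  profile <- beam_profile(probe, elev_sigma = scn$elev_sigma)
  phant <- if (!is.null(scn$phantom)) make_phantom(scn$phantom, scn$seed) else NULL
  sc <- scene(med, phant)
  ex <- scn$experiment
  files <- character(0)
  put <- function(f) files <<- c(files, f)

  if (ex$type == "single-frame") {
    acq <- acquire_frame(probe, sc, scn$device, profile = profile)
    write_trigger_csv(acq$log, file.path(out_dir, "triggers.csv"))
    put(file.path(out_dir, "triggers.csv"))
    bm <- form_bmode(acq$frame)
    write_pgm(bm$pixels, file.path(out_dir, "bmode.pgm"))
    put(file.path(out_dir, "bmode.pgm"))
    jsonlite::write_json(
      list(lateral_extent_mm = diff(range(bm$line_x)) * 1e3,
           axial_extent_mm = max(bm$depth_axis) * 1e3,
           dynamic_range_db = bm$dynamic_range_db,
           trigger_count = acq$log$count),
      file.path(out_dir, "bmode.json"), auto_unbox = TRUE, digits = NA)
    put(file.path(out_dir, "bmode.json"))
  } else if (ex$type == "sweep") {
    offs <- parse_quantity(unlist(ex$offsets_mm %||% seq(-9, 9, by = 1)))
    sw <- midplane_sweep(probe, sc, scn$device, offs,
                         repeats = ex$repeats %||% 10, seed = scn$seed,
                         noise_sd = parse_quantity(ex$noise_sd %||% 0),
                         profile = profile)
    utils::write.csv(as.data.frame(sw), file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    put(file.path(out_dir, "sweep.csv"))
    est <- localize_midplane(sw, "count")
    jsonlite::write_json(
      list(estimate_mm = est$estimate_mm,
           detectable_range_mm = detectable_range(sw)),
      file.path(out_dir, "midplane.json"), auto_unbox = TRUE, digits = NA)
    put(file.path(out_dir, "midplane.json"))
  } else if (ex$type == "grid") {
    tab <- parameter_grid(
      probe, sc, scn$device,
      tx_powers = unlist(ex$tx_powers %||% c(0.5, 1)),
      tx_apertures = unlist(ex$tx_apertures %||% c(16, 32, 64)),
      focus = unlist(ex$focus %||% c(TRUE, FALSE)),
      gains_db = unlist(ex$gains_db %||% seq(5, 25, by = 5)),
      elev_sigma = scn$elev_sigma
    )
    utils::write.csv(tab, file.path(out_dir, "grid.csv"), row.names = FALSE)
    put(file.path(out_dir, "grid.csv"))
  } else if (ex$type == "mmode") {
    n_frames <- ex$n_frames %||% 40
    fps <- parse_quantity(ex$frame_rate %||% probe$frame_rate %||% 20)
    frames <- lapply(seq_len(n_frames) - 1, function(k) {
      acquire_frame(probe, sc, scn$device, profile = profile,
                    frame_start = k / fps, frame_index = k + 1)$frame
    })
    sched <- line_schedule(probe)
    li <- ex$line_index %||% which.min(abs(sched$line_x - scn$device$position[1]))
    mm <- extract_mmode(frames, li)
    write_pgm(log_compress(mm$columns), file.path(out_dir, "mmode.pgm"))
    put(file.path(out_dir, "mmode.pgm"))
    jsonlite::write_json(
      list(line_index = li, frame_rate = fps, n_frames = n_frames),
      file.path(out_dir, "mmode.json"), auto_unbox = TRUE, digits = NA)
    put(file.path(out_dir, "mmode.json"))
  } else if (ex$type == "inject") {
    if (is.null(scn$pattern)) stop("inject experiment needs a pattern", call. = FALSE)
    dev <- scn$device
    dev$mode <- "pattern"
    c0 <- med$assumed_c
    min_gap <- dev$pulse_cycles / dev$pulse_freq
    plan <- if (scn$pattern$anchor == "absolute") {
      rasterize_sync(scn$pattern, probe, dev$position, c0, min_gap = min_gap)
    } else {
      probe_sched <- line_schedule(probe)
      ref_line <- which.min(abs(probe_sched$line_x - dev$position[1]))
      d0 <- sqrt(sum((dev$position - c(probe_sched$line_x[ref_line], 0, 0))^2))
      rasterize_relative(scn$pattern, probe$line_period,
                         list(line = ref_line, t_trigger = d0 / c0),
                         probe, c0, min_gap = min_gap)
    }
    utils::write.csv(
      data.frame(line = plan$firings$line, time_us = plan$firings$t * 1e6,
                 amplitude = plan$firings$amplitude),
      file.path(out_dir, "plan.csv"), row.names = FALSE)
    put(file.path(out_dir, "plan.csv"))
    acq <- acquire_frame(probe, sc, dev, plan = plan, profile = profile)
    bm <- form_bmode(acq$frame)
    write_pgm(bm$pixels, file.path(out_dir, "bmode.pgm"))
    put(file.path(out_dir, "bmode.pgm"))
  } else if (ex$type == "modes") {
    tab <- do.call(rbind, lapply(
      c("harmonic", "general", "resolution", "penetration"), function(mname) {
        p <- linear_probe(
          n_elements = probe$n_elements, pitch = probe$pitch, fs = probe$fs,
          lines_per_frame = probe$lines_per_frame,
          tx_aperture = probe$tx_aperture, focus_depth = probe$focus_depth,
          tx_power = probe$tx_power, line_period = probe$line_period,
          max_depth = probe$max_depth, tx_cycles = probe$tx_cycles,
          mode = mname)
        prof <- beam_profile(p, elev_sigma = scn$elev_sigma)
        dev_on <- scn$device; dev_on$mode <- "echo"
        dev_off <- scn$device; dev_off$mode <- "off"
        on <- acquire_frame(p, sc, dev_on, profile = prof)$frame
        off <- acquire_frame(p, sc, dev_off, profile = prof)$frame
        mr <- snr_cnr_from_frames(on, off)
        data.frame(mode = mname, snr = mr$snr, cnr = mr$cnr)
      }))
    utils::write.csv(tab, file.path(out_dir, "modes.csv"), row.names = FALSE)
    put(file.path(out_dir, "modes.csv"))
  } else {
    stop("unknown experiment type '", ex$type, "'", call. = FALSE)
  }

  invisible(write_manifest(files, out_dir))
}

#' Generate ready-made scenario files
#'
#' Writes a self-contained scenario YAML for one of the named desk-scale
#' setups: `echo-basic` (water tank, echo mode), `jhu-pattern`
#' (multi-letter bitmap injection), `midplane-bars` (trigger-count bar
#' indicator), `aluminum-layer` (1-inch fast layer between probe and
#' element), `deep-tissue` (attenuating phantom, element at 8.5 cm) and
#' `mode-comparison` (SNR/CNR across imaging modes).
#'
#' @param kind Fixture name.
#' @param seed Seed stored in the scenario.
#' @param dir Directory to write into.
#' @return Path of the scenario file written.
#' @export
make_fixtures <- function(kind = c("echo-basic", "jhu-pattern",
                                   "midplane-bars", "aluminum-layer",
                                   "deep-tissue", "mode-comparison"),
                          seed = 1, dir = ".") {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(kind, ".yaml"))
  water <- list(layers = list(list(thickness = "1 m", c = 1480, attenuation = 0)),
                assumed_c = 1480)
  base_device <- list(position = c("0 mm", "0 mm", "40 mm"), mode = "echo")
  scn <- switch(kind,
    "echo-basic" = list(
      probe = list(lines_per_frame = 128, fs = "40 MHz"),
      medium = water, device = base_device,
      experiment = list(type = "single-frame"), seed = seed
    ),
    "jhu-pattern" = list(
      probe = list(lines_per_frame = 128, fs = "40 MHz"),
      medium = water,
      device = utils::modifyList(base_device, list(mode = "pattern")),
      pattern = list(
        bitmap = c("###.#.#.#.#",
                   "..#.#.#.#.#",
                   "..#.###.#.#",
                   "#.#.#.#.#.#",
                   "###.#.#.###"),
        line0 = 40, depth0 = "25 mm", dline = 4, ddepth = "2 mm"
      ),
      experiment = list(type = "inject"), seed = seed
    ),
    "midplane-bars" = list(
      probe = list(lines_per_frame = 128, fs = "40 MHz"),
      medium = water,
      # threshold chosen so the detectable range is about +/-8 mm with the
      # default 3 mm elevational beam at 19 dB gain
      device = utils::modifyList(base_device, list(threshold = 0.5)),
      experiment = list(type = "sweep",
                        offsets_mm = seq(-9, 9, by = 1), repeats = 10),
      seed = seed
    ),
    "aluminum-layer" = list(
      probe = list(lines_per_frame = 128, max_depth = "70 mm", fs = "40 MHz"),
      medium = list(layers = list(
        list(thickness = "20 mm", c = 1480, attenuation = 0),
        list(thickness = "25.4 mm", c = 6320, attenuation = 0),
        list(thickness = "1 m", c = 1480, attenuation = 0)
      ), assumed_c = 1480),
      device = list(position = c("0 mm", "0 mm", "60 mm"), mode = "echo",
                    rx_gain_db = 30),
      experiment = list(type = "single-frame"), seed = seed
    ),
    "deep-tissue" = list(
      probe = list(lines_per_frame = 128, max_depth = "95 mm",
                   mode = "penetration", fs = "40 MHz",
                   focus_depth = "80 mm"),
      medium = list(c = 1540, attenuation = 0.5, assumed_c = 1540),
      phantom = list(z_range = c("5 mm", "90 mm"), density = 20),
      device = list(position = c("0 mm", "0 mm", "85 mm"), mode = "echo",
                    rx_gain_db = 40, pulse_freq = "6 MHz"),
      experiment = list(type = "single-frame"), seed = seed
    ),
    "mode-comparison" = list(
      probe = list(lines_per_frame = 128, fs = "40 MHz"),
      medium = list(c = 1540, attenuation = 0.3, assumed_c = 1540),
      phantom = list(density = 30),
      device = c(base_device, list(pulse_freq = "9 MHz")),
      experiment = list(type = "modes"), seed = seed
    )
  )
  yaml::write_yaml(scn, path)
  path
}
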