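Package: activeecho
Title: Simulation of Active-Echo Ultrasound Tool Tracking and Pattern Injection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software testbed for active-echo guidance of interventional tools
    under B-mode ultrasound. Simulates linear-array acquisition (line scheduling,
    Gaussian transmit beams, RF line synthesis, envelope detection and log
    compression) coupled to a catheter-mounted active-echo element that receives
    beacon pulses, triggers against a threshold with a latch, and fires pulses
    after a configurable loop delay. Implements blink (time) modulation,
    frequency modulation with matched-filter template extraction, trigger-count
    and amplitude-based image mid-plane localization, arbitrary virtual-pattern
    injection under both frame-synchronized and line-period-estimation timing,
    and the associated evaluation computations (elevational sweeps, detectable
    range, parameter grids, SNR/CNR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
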