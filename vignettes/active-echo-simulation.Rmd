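---
title: "Active-echo ultrasound tracking: the simulation model and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-echo ultrasound tracking: the simulation model and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activeecho)
```

## The problem

Interventional tools -- catheters, needles -- are poorly visualized in
conventional B-mode ultrasound, and even when visible their position along
the *elevational* axis (perpendicular to the imaging plane) is ambiguous at
the millimetre-to-centimetre scale of the acoustic beam width. An
*active-echo* element is a small piezo transducer at the tool tip that
closes the loop with the scanner acoustically: it receives the scanner's
beacon pulses, triggers against a threshold, and fires its own pulse back
with a controlled delay, frequency and amplitude. The scanner, unaware,
beamforms that pulse like any echo and renders a bright spot -- or, with
per-line timing control, any virtual pattern -- into its own image. On top
of this loop sit four techniques that this package implements and
evaluates end to end:

* **time modulation** -- gating the feedback with a blink period so the
  spot flashes against static tissue texture;
* **frequency modulation** -- firing at a frequency distinct from the
  imaging carrier so a matched filter can extract the device signal from
  RF data;
* **mid-plane detection** -- using the trigger count per frame (many
  overlapping neighbouring beams exceed a low threshold near the beam
  centre) or the received peak amplitude to localize the element on the
  image mid-plane;
* **arbitrary pattern injection** -- computing per-pixel fire times
  `t = 2*y/c - d/c` so that chosen virtual pixels appear at chosen image
  coordinates, with or without a frame synchronization signal.

Everything here is simulated: the package contains a simplified
linear-array acquisition model coupled to the device model, so every claim
the analysis makes can be checked against known ground truth.

## The acquisition model

Coordinates are `x` lateral (along the array), `e` elevational (the image
plane is `e = 0`), `z` axial (depth, 0 at the probe face); all internal
units are SI (metres, seconds, hertz), and scenario files may use unit
suffixes (`"40 mm"`, `"200 us"`, `"10 MHz"`).

A frame is `lines_per_frame` A-lines laid out uniformly across the array
footprint, fired one per `line_period`. Each line is a single
pre-beamformed RF record: no per-element channel data or receive
beamforming is modeled, because every mechanism of interest depends only
on line timing and amplitude. The transmit pulse is a Gabor pulse
(Gaussian-windowed cosine, default 2 cycles) *centred* on its nominal
time, so a point scatterer's envelope peak falls exactly on the round-trip
sample -- the axial-accuracy contract the tests rely on.

The transmit beam is a separable Gaussian. Laterally an unfocused aperture
has constant `sigma = aperture_width/4`; a focused aperture follows a
hyperbolic waist with minimum `lambda * focus_depth / aperture_width` and
Rayleigh range `pi * w0^2 / lambda`. Elevationally the beam is Gaussian
with constant `elev_sigma` (default 3 mm) -- this width is precisely what
mid-plane detection measures, so it is an explicit profile parameter. The
on-axis peak encodes transmit power, the aperture (relative to a
32-element reference) and, for focused beams, the waist gain
`sqrt(sigma_unfocused / sigma(z))`.

Media are ordered layers `(thickness, c, attenuation)` traversed by
straight rays (no refraction), with amplitude attenuation
`10^(-alpha * f_MHz * path_cm / 20)` and no dispersion. The scanner maps
time to depth with its own display speed `assumed_c`, which is how a fast
intermediate layer (the 1-inch aluminium plate fixture, c = 6320 m/s in
1480 m/s water) makes the spot appear shallower by exactly
`L * (1 - c_water / c_al)` -- about 19.4 mm for the default fixture -- a
closed form the acceptance tests check to one axial sample.

Every RF line is band-pass filtered to the probe's receive band with a
zero-phase FFT filter with raised-cosine edges (1 MHz transitions). Two
properties of this choice carry the analysis: it is *exactly linear*, so
the on/off frame difference equals the device contribution to rounding
error (the basis of template acquisition), and it is *symmetric*, so
envelope peaks stay on their samples. A hard brick-wall edge was rejected
because its sinc ringing stretched template supports by an order of
magnitude.

Imaging-mode presets (`general`, `resolution`, `penetration`, `harmonic`)
only do frequency/band bookkeeping. In harmonic mode tissue echoes are
rendered at twice the transmit frequency scaled by `harmonic_fraction`
(default 0.1); no nonlinear propagation is modeled. The device pulse
(default 9 MHz) then stands far out of the weak tissue harmonic
background, reproducing the qualitative mode ordering of spot
conspicuity.

## The device model and a timing idealization

The device chain is: beacon pressure x sensitivity x `10^(gain_db/20)` x
directivity. Directivity is `max(cos^2(angle), 0.05)` about the cylinder
axis -- no pattern was available, and the only requirement is that
triggering stays achievable at every insertion angle with gain
adjustment. The comparator triggers on `|v| >= threshold` with a latch
that resets at each line start: oscillation protection lives *within* a
line, because multiple triggers per frame across lines are exactly what
the trigger-count method needs.

One deliberate idealization deserves emphasis. A threshold comparator on
the sampled waveform fires at the pulse's *leading edge* -- up to half a
pulse length before the beacon's envelope peak, and the offset depends on
the threshold. Carried into the firing time, that jitter would smear the
echo spot by several samples and make the zero-delay spot miss the
element's true position. The acquisition loop therefore timestamps
triggers at the *beacon arrival* (pulse-centre) time, so echo-mode fire
times exceed the beacon arrival by exactly `loop_delay`, and with
`loop_delay = 0` the spot coincides with the element's image position to
one axial sample. The sampled-trace comparator is still provided
(`trigger_decision()`, tested against a brute-force first-crossing
oracle) for analysing arbitrary traces. With the default 0.6 us loop
delay in water the spot sits `c * delay / 2 = 0.444 mm` deep of the
element -- the simulator follows this physics exactly.

Received active-echo packets are weighted by an unfocused whole-array
receive acceptance (`sigma = array_width/4`, Gaussian in the element's
lateral offset from the listening line, Gaussian in elevation). This is
wide enough that pattern pixels injected on lines far from the catheter
stay bright, yet makes the line nearest the element record the strongest
packet, so the plain echo spot is laterally localized on the element's
line.

## Pattern injection

Method 1 (frame synchronization available): each absolute pixel
`(line j, depth y)` becomes one firing at `t = 2*y/c - d_j/c` where `d_j`
is the element-to-aperture-centre distance of line `j`, computed from
geometry. Pixels with `2*y < d` are physically unreachable and are
skipped with a warning rather than aborting -- a partial pattern is more
useful than none. Firings closer than one pulse duration on a line are
merged with summed intensity, since a physical element cannot overlap
firings.

Method 2 (no synchronization): the received beacon is the clock. The
A-line period is estimated as the median of successive trigger-time
differences after dividing each difference by its nearest-integer line
gap; the snapping base is the smallest observed difference (identifiable
whenever at least one adjacent-line pair triggers, which a
trigger count >= 2 guarantees in practice) or a caller-supplied prior
from an earlier frame. A pixel at `(dline, ddepth)` relative to the
element fires `dline * period + 2*ddepth/c` after the reference trigger.
With the exact period supplied, methods 1 and 2 produce identical fire
times for element-relative pixels to a fraction of a sample (the residual
is the second-order geometry term `(d_j - d_0)/c`, nanoseconds for
nearby lines).

The trigger-count bar indicator renders `ceil(count / counts_per_bar)`
element-relative bars, so the bar stack grows monotonically as the tool
approaches the mid-plane.

## Analysis definitions

The named SNR/CNR quantities follow the three ingredients their source
experiment names: *DiffSignal* (echo-on minus echo-off image),
*background* (the echo-off image) and a 50 x 50-pixel *surrounding area*
around the spot. The exact formulas were not printed; this package
declares the standard forms

```
SNR = mean(DiffSignal over spot) / sd(background over window)
CNR = |mean(on over spot) - mean(background over window)| / sd(background over window)
```

with the spot defined as pixels where DiffSignal is at least half its
maximum (the spot extent was likewise undefined), `sd` the sample
standard deviation, and CNR on the raw on-image. Because each B-mode is
normally normalized to its own maximum, `snr_cnr_from_frames()` forms the
on/off pair with a *shared* reference; without this the spot would pin
both frames' scales and the comparison would be meaningless.

Sweeps emulate the translation stage moving the probe relative to the
fixed element, 10 repeats per position by default with re-seeded
measurement noise; positions with a mean count above 40 are flagged and
excluded from derived fits (a very wide spot distorts localization).
Trigger counts are integers and plateau near the maximum, so the count
and amplitude localizers return the plateau midpoint, refined
parabolically only when the maximum is a single grid point -- for any
symmetric noiseless sweep the estimate is exactly 0. The threshold
localizer interpolates the two crossings of `q * max` linearly; for a
Gaussian elevational profile the half-width is `sigma * sqrt(2*ln(1/q))`
(0.459 sigma at q = 0.9), which is the closed form the parameter-recovery
tests invert.

The detectable range interpolates the outermost non-zero count linearly
to the first zero on each side. The default sweep fixture sets the
trigger threshold to 0.5 V, chosen so that with the default 3 mm
elevational beam at 19 dB gain the range comes out near +/-8 mm -- the
regime the method is designed for -- rather than tuned to any particular
printed figure.

## What the generator emulates, and what it does not

The synthetic scenes are uniform boxes of point scatterers at a chosen
density with Rayleigh/uniform/lognormal reflectivities and optional
bright inclusions, fully reproducible from `(spec, seed)`. They provide a
speckle-like background with controllable statistics -- enough to
exercise template extraction, SNR/CNR and visualization contrast. They do
*not* reproduce real tissue: no spatially correlated speckle, no
aberration, no motion, no reverberation clutter, and the Gaussian beam
carries no side lobes or grating lobes. Passing tests therefore
demonstrate correctness of the mechanisms (timing, geometry, counting,
filtering, metric arithmetic), not image realism; absolute trigger
counts or SNR values from hardware with unknown acoustic fields are out
of reach by construction, and only defined computations and orderings
are asserted.

Two further model limits are worth naming. First, with the declared
focused-waist law `w0 = lambda * z_f / aperture_width`, an element
*exactly* at the focal depth can see its trigger count fall as the
aperture grows (the waist narrows faster than the power grows); the
aperture-monotonicity ordering is therefore exercised with the element
near, not precisely at, the focus -- which is also the realistic
operating condition, since the insertion depth is only approximately
known. Second, elastic/shear-wave behaviour in solid layers is ignored;
the aluminium fixture models timing only.

## Numerical choices and problem sizes

Defaults: 128 elements at 0.3 mm pitch, 256 lines/frame (tests use 64 or
fewer), 40 MHz RF sampling, 200 us line period, 50 dB display dynamic
range, 2-cycle pulses, loop delay 0.6 us, 19 dB receive gain, 150 V /
12.5 ns pulser limits. The test and acceptance workloads use 16-64-line
frames, 30-50 mm depths, sweeps of 19-25 positions with 1-10 repeats,
and 20-pixel random patterns -- sizes chosen so the whole suite runs in
well under a minute while every contract is still exercised at full
sampling resolution. Determinism is strict: phantoms and noise draw from
private RNG streams (`with_seed`), so identical seeds give bit-identical
fields, manifests hash-equal across runs, and noiseless sweeps are
exactly reproducible.

## Reproducing the headline quantities

`scripts/acceptance.R --seed <int> --out <path>` re-runs the main
computations from scratch against the installed package -- injection
geometry errors, the fire-time closed form, the loop-delay spot shift,
sweep localization and detectable range, elevational-width recovery,
template extraction and matched filtering, SNR/CNR at two drive
voltages, the aluminium-layer apparent depth, blink run lengths, and the
two-method injection agreement -- and writes them as JSON. The README
shows a worked example with the numbers it prints.
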