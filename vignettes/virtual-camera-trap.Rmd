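---
title: "A virtual camera trap: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual camera trap: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapsim)
```

`trapsim` is a hardware-free re-creation of a customisable camera-trap
platform built around *confirmatory sensing*: a passive-infrared (PIR)
trigger whose captures are cross-checked against a radar log and, above all,
against a recent time-lapse image by on-board background subtraction. This
vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic data do and do not emulate, and
the design decisions taken where the design was genuinely open.

## The problem

A PIR sensor fires on the combination of a heat signature (thermal contrast
between animal and background) and movement. Two failure modes dominate in
the field:

* **False positives** — the trap records an image containing no animal. The
  characteristic mechanism on a platform whose PIR detection zone is *wider*
  than the camera's field of view (FOV) is a warm body inside the zone but
  outside the picture. Such images waste storage, battery and, most of all,
  analyst time.
* **False negatives** — an animal in view produces no image: it moved too
  slowly to trip the PIR (birds feeding on the ground), rain masked its
  thermal contrast, or (for radar confirmation) its radar cross-section was
  too small.

The platform's remedy is to compare every motion-activated image with the
most recent scheduled time-lapse image inside a Region of Interest (ROI):
images similar to the background are classified as false positives and can
be deleted or merely flagged. `trapsim` reproduces this whole pipeline on
synthetic scenes with exact ground truth, so each mechanism can be asserted
rather than anecdotally observed.

## Scene and geometry model

The arena is a flat rectangle (defaults 6 m × 8 m with a conceptual 1 m
grid — the dimensions of a roof-top test plot), with the trap at the middle
of one short edge, `trap_position = c(3, 0)`, mounted 0.8 m up and looking
straight into the arena (`heading = 90` degrees). Both sensor footprints are
symmetric angular sectors around the heading:

| parameter | default | units | rationale |
|---|---|---|---|
| `camera_fov_halfangle` | 27 | degrees | a small single-board camera's ~54° horizontal FOV |
| `camera_max_range` | 8 | m | arena depth |
| `pir_fov_halfangle` | 45 | degrees | wider than the camera — the false-positive-generating configuration |
| `pir_max_range` | 9 | m | upper end of the radar range gate |

The original hardware's exact angles are not published; these are
configurable defaults chosen to preserve the *ordering* (PIR zone ⊇ camera
FOV) that drives the phenomena of interest, not a claim about any particular
unit. The constructor enforces that ordering, which gives the package-wide
invariant `in_camera_fov ⇒ in_pir_zone`.

Frames are single-channel 0–255 intensity grids (default 320 × 240),
produced by a scaled orthographic top-down map from arena metres to pixels.
A perspective camera model would change blob positions and sizes but nothing
about the triage mathematics, which is intensity-difference based; grayscale
and orthographic are deliberate simplifications. A rendered frame is

* a background: `background_mean` (120) + a linear illumination drift of
  `illumination_drift_amplitude` (10) intensity units per hour + Gaussian
  pixel noise with `noise_sigma` (2);
* plus, for every track currently inside the **camera** FOV, an additive
  disc of radius `body_radius_px` (6 px) and amplitude `thermal_contrast`
  (80). The same quantity serves as the PIR heat signature and as the blob
  amplitude — a deliberate conflation: the render emulates an
  infrared-sensitive camera, and one number per animal keeps the sensing
  and imaging stories consistent.

Per-frame noise is seeded by an arithmetic mix of the scene seed and the
frame timestamp, so the same instant re-renders bit-identically. This is
what makes the out-of-view mechanism exact: a frame captured while the
animal is inside the PIR zone but outside the FOV is *bit-identical* to the
empty-scene render, not merely similar.

## Tracks and ground truth

`generate_tracks()` produces bounded correlated random walks sampled on a
regular clock (default 1 s): per-sample speed is a mixture of a "dwell"
mode (probability 0.3, speed uniform on [0, 0.02] m/s — a feeding bird,
below the PIR's minimum speed) and a moving mode (gamma with mean 0.5 m/s,
a walking bird); headings diffuse with 40° standard deviation per step and
reflect off the walls. For campaigns that need controlled geometry,
`crossing_track()` (straight, constant speed) and `arc_track()` (constant
radius around the trap, sweeping an angular-offset band) script visits that
pass through the FOV or deliberately skirt it inside the PIR-only flank.
`zone_crossing_tracks()` interleaves the two kinds on an evenly spaced,
seed-jittered schedule starting after the first time-lapse background
exists, with every start/end point outside the PIR zone.

`make_ground_truth()` plays the role of the reference video camera in a
field trial: each contiguous run of in-zone samples becomes one event,
flagged in-FOV if *any* of its samples was within the camera's sector. Event
timing is therefore quantised by the sampling interval; the geometric test
asserts a diameter crossing's event duration to within one interval.

## Sensor models

Detection is deterministic given a track sample:

* PIR: inside the PIR sector and range, `speed >= min_speed` (0.05 m/s) and
  `thermal_contrast × rain_attenuation >= contrast_threshold` (10).
* Radar: `min_range` (2.4 m) ≤ range ≤ `max_range` (9 m) — a commodity
  10.5 GHz module's adjustable gate — and
  `radar_cross_section >= min_cross_section` (1; the default animal
  cross-section of 0.5 sits below it, emulating how little a radar confirms
  for small-bodied birds). The radar model has no angular restriction, since
  only its range behaviour is specified for the original platform.

Every documented miss mechanism is a threshold effect, so determinism makes
the oracles exact and detection automatically monotone in each threshold.
The magnitudes of `min_speed` and of rain attenuation were never quantified
for the original platform; they are free parameters with the defaults above.
A probabilistic detection layer would be a straightforward extension but is
deliberately absent from the reference behaviour.

## The controller

The capture loop is event-driven over simulated time:

* time-lapse at `t = k · timelapse_interval` for `k ≥ 1` — the clock starts
  at the first interval boundary, so there is **no capture at t = 0**; a
  fixed convention was needed for the schedule arithmetic
  (`floor(duration/interval)` captures) and this one maximises the age
  symmetry of backgrounds;
* a motion capture at `t_event + trigger_latency` (0.44 s, a measured
  prototype latency retained as a simulation parameter) whenever the PIR
  fires at a sample instant, the time of day is inside an active window, and
  at least `min_motion_interval` (5 s) has elapsed since the **previous
  capture** (capture-to-capture; whether the original spacing was
  trigger-to-trigger is unrecorded, so one convention is implemented and
  documented). The scene is rendered at the *capture* instant, so a fast
  target can leave the FOV between trigger and shutter — early/slow
  triggering falls out of the model rather than being special-cased;
* when a trigger and a time-lapse coincide, the time-lapse is captured first
  and immediately serves as the motion frame's background (maximum
  freshness, deterministic ordering);
* a motion capture made before any time-lapse exists is `pending` — never
  auto-deleted, because triage requires "a recent time-lapse image" and a
  cold start has none;
* by default each time-lapse image is deleted once superseded
  (`keep_background = FALSE`), retaining only the latest — the storage-saving
  behaviour of the original — while its catalog row and log line survive.

Suppressed triggers, radar detections, triage verdicts and background
deletions are all logged, which makes count conservation
(`captures = triggers − suppressed`) checkable from the log alone.

The configuration file is a flat `key: value` text document (one key per
line, `#` comments) mirroring how the hardware reads "a text file specifying
variable values"; unknown keys are rejected by name, missing keys take the
documented defaults.

## Triage

Two thresholds, not one: a per-pixel intensity delta (`diff_pixel_delta`,
default 12) binarises `|motion − background|` inside the ROI, and the count
of set pixels is compared against `diff_count_threshold` (default 50),
strictly below which the image is a false positive. The published
description names only "a difference threshold", but the published
difference images are binary masks, which implies a per-pixel binarisation
step must exist; both knobs are therefore exposed. The comparison is a plain
absolute difference with no blur or morphology — the simplest procedure
consistent with the published mask images is the reference behaviour (the
original's exact cleanup steps are unpublished). The raw count, not a
fraction of the ROI, is thresholded. Boundary conventions: difference
strictly greater than the delta sets a mask pixel; a count strictly below
the threshold is a false positive, so `count_threshold = 0` accepts
everything; ROI rectangles are 0-based and half-open; background selection
takes the time-lapse frame with the greatest timestamp ≤ t.

With the default numbers the scheme is effectively deterministic on
synthetic scenes: pixel differences between two same-scene renders are
`N(0, σ√2)` plus at most 0.33 intensity units of drift across a 120 s
background gap, so `delta = 12 = 6σ` leaves a per-pixel exceedance
probability near 2×10⁻⁵ — a handful of pixels per 320 × 240 frame against a
count threshold of 50 — while a full blob contributes ~113 pixels at
contrast 80. The package's end-to-end guarantee is stated (and tested) in
exactly those terms: when the per-pixel delta exceeds 5 × noise sigma and
blobs have contrast ≥ 2 × delta and area ≥ the count threshold, every
out-of-view false positive is flagged and no capture whose frame really
contains a qualifying blob is discarded.

One behaviour deserves emphasis: a motion capture taken while a real visitor
is still *approaching* the FOV (early triggering by the wider PIR zone)
contains no blob and is flagged as a false positive even though the event
matching counts it as a true positive. That is the correct verdict at image
level — the image genuinely shows nothing — and mirrors how such images
would be treated in practice.

## Metadata

Filenames are `YYYYMMDDThhmmss[_LABEL]_{M|T}[_k].jpg` (label validated to
filesystem-safe characters; `_k` resolves same-second collisions). JPEG
metadata is genuine EXIF, written by a purpose-built minimal APP1 writer:
the full tag mapping is serialised as JSON into the ImageDescription slot
(preserving number/flag types across a round trip) and the timestamp is
mirrored into the standard DateTime slot, so ordinary image-management
software can read both; one test verifies readability with an independent
image library. Embedding splices a header segment only — pixel data is
bit-identical before and after. PNG has no EXIF container, so tags go to a
JSON sidecar. The CSV catalog is comma-separated with a header row and
ISO-8601 timestamps, one append-only row per capture (kept *or* deleted),
covering every capture-record field.

## Evaluation

`match_captures()` scores a trial with a ±`window` rule (default 5 s — the
same spacing that was imposed in the field precisely to make image-to-event
allocation unambiguous): a motion capture overlapping an in-FOV event is a
true positive, any other motion capture is a false positive, and an in-FOV
event with no overlapping capture is a false negative. TP/FP are counted
per *image* and FN per *event*, matching how trial tables count images
recorded but detections missed; a long visit photographed twice therefore
yields two true positives, not one plus a false positive. (An earliest-first
allocation of captures to events is also returned for reporting.) How
multi-animal visits should be counted as one or several "potential
detections" has no published answer; one event per track per zone-entry is
this package's convention. `fp_after_triage` — false positives whose triage
verdict wrongly remained `true-capture` — is the quantity the whole triage
design aims to drive to zero, and on the seeded campaigns of
`zone_crossing_tracks()` it is zero.

## Problem sizes and numerical choices

The test suite and the acceptance script run synthetic campaigns of three
30-minute trials (1 s track sampling, 320 × 240 px frames, ~27 captures per
trial), with unit tests on 64 × 48 frames; brute-force difference-count
oracles run exhaustively on frames up to 64 × 64. These sizes were chosen so
the full pipeline — including the double-loop oracles — completes in well
under a minute while still containing every phenomenon of interest (multiple
background refreshes, both capture kinds, both triage verdicts, suppressed
triggers). All randomness flows from explicit integer seeds: track
generation and visit jitter restore the caller's RNG state, and frame noise
is seeded per (scene seed, timestamp), below 2³¹.

## What the synthetic data do not show

Passing tests demonstrate the *logic* of the platform, not field
performance. The renderer has no perspective, occlusion, shadows, moving
vegetation, rain streaks, sun glint or exposure changes — the very nuisances
that make real background subtraction hard; illumination drift is linear
rather than diurnal; blobs are rigid discs, animals never overlap the ROI
boundary ambiguously, and PIR physics is reduced to three thresholds. Real
deployments should expect a non-trivial per-pixel delta/threshold tuning
problem that the clean synthetic noise floor hides. The simulator is a test
harness for the decision machinery, and the bundled three-day field-trial
counts are the empirical anchor for what that machinery achieved on real
birds.
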