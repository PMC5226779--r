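# trapsim

A virtual camera trap. `trapsim` re-creates, entirely in software, a
customisable wildlife camera-trap platform whose defining feature is
*confirmatory sensing*: a passive-infrared (PIR) trigger that is
cross-checked by a radar log and by on-board **background subtraction** of
each motion-activated image against a recent time-lapse image, so that
false-positive images (a warm body inside the PIR detection zone but outside
the camera's field of view) can be flagged or deleted at the point of
collection.

It is written for two audiences:

* **ecologists and camera-trap methodologists** who want to study trigger
  scheduling, detection-zone geometry and false-positive/false-negative
  accounting with known ground truth, before (or instead of) deploying
  hardware;
* **developers of trap firmware/processing pipelines** who need a
  reproducible test bed: every component — scene renderer, sensor models,
  trigger controller, triage, metadata cataloguing, evaluation — is an
  ordinary R function with deterministic, seeded behaviour.

## What it implements

* **Scene simulation** — a seeded flat arena (default 6 m × 8 m, the size of
  a roof-top trial plot) viewed top-down by a trap at its edge; animal tracks
  are bounded random walks with a "dwell" (feeding) mode, or scripted
  straight/arc paths; frames are grayscale backgrounds (mean + illumination
  drift + per-frame seeded noise) with a disc blob composited for every
  animal inside the camera field of view. Ground truth records when each
  track was inside the PIR zone and whether it was ever in view.
* **Sensor models** — PIR: angular zone + range + minimum speed + thermal
  contrast threshold (rain attenuates contrast); radar: range gate
  (default 2.4–9 m) + minimum radar cross-section. All the field-observed
  miss mechanisms (slow feeding birds, rain-masked signatures, small-bodied
  targets, out-of-range) are threshold effects and therefore exactly
  testable.
* **Controller** — flat `key: value` configuration file; time-lapse captures
  every `timelapse_interval` (default 120 s); motion captures at
  `trigger + trigger_latency` (default 0.44 s) with a minimum
  capture-to-capture spacing (default 5 s); active-hours gating; radar
  activity logged and cross-referenced to each capture.
* **Triage** — background subtraction of each motion frame against the most
  recent time-lapse frame within a Region of Interest; pixels differing by
  more than `diff_pixel_delta` are counted; counts strictly below
  `diff_count_threshold` classify the image as a false positive, which is
  deleted or flagged per policy.
* **Metadata** — self-describing filenames
  (`YYYYMMDDThhmmss[_LABEL]_{M|T}[_k].jpg`), EXIF tags embedded in JPEG
  headers (JSON in ImageDescription + standard DateTime; readable by
  standard image software), PNG sidecar fallback, and an append-only CSV
  catalog.
* **Evaluation** — matching of capture records against ground-truth events
  within a ±window into true-positive / false-positive / false-negative
  counts per trial, plus `fp_after_triage` (blanks that triage failed to
  flag), and field-wise aggregation across trials.

## Worked example

```r
library(trapsim)

geometry <- trap_geometry()            # trap at (3, 0) m, camera 27deg/8m, PIR 45deg/9m
scene    <- scene_config(rng_seed = 1) # 6x8 m arena, 320x240 px, noise sd 2
config   <- trap_config()              # 120 s time-lapse, 5 s spacing, flag policy

# visits that cross the detection zone in and out of the camera's view
tracks <- zone_crossing_tracks(geometry, duration = 1800, seed = 1)
truth  <- make_ground_truth(tracks, geometry)
run    <- run_trap(config, scene, geometry, tracks, duration = 1800)
print(run)
#> <trap_run: 1800 s, 12 motion + 15 timelapse captures, 133 log lines>
#>   motion triage: false-positive=9, true-capture=3

match_captures(run$captures, truth, window = 5)
#>   trial_id true_positive false_positive false_negative fp_after_triage
#> 1    trial             8              4              0               0
```

Reading the output: the trap recorded 12 motion-activated images. Four of
them were triggered while a bird was inside the PIR detection zone but
outside the camera's view (`false_positive = 4`) — their frames are blank,
and background subtraction flagged every one (`fp_after_triage = 0`). Eight
images coincide with in-view visits (`true_positive = 8`); several of those
were taken while the bird was still approaching the field of view (early
triggering by the wider PIR zone), so their frames are also blank and triage
marks them too — only the 3 frames that actually contain a blob keep the
`true-capture` verdict. No in-view visit went unrecorded
(`false_negative = 0`).

A shell front end wraps the same functions:

```sh
exec/trapsim run --config trap.conf --scene scene.yaml --duration 600 --out out/
exec/trapsim triage --motion out/ --timelapse out/ --pixel-delta 12 --count-threshold 50 --policy flag --out report.csv
exec/trapsim evaluate --captures out/captures.csv --truth out/truth.csv --window 5 --out table.csv
```

## Package layout

```
R/scene.R       arena, geometry, tracks, rendering, ground truth
R/sensors.R     PIR / radar / environment models
R/controller.R  trap configuration parsing and the capture loop
R/triage.R      ROI background subtraction and the false-positive policy
R/metadata.R    filenames, EXIF embedding/extraction, CSV catalog
R/exif.R        minimal EXIF APP1 writer/reader used by metadata
R/evaluate.R    confusion counts, matching, aggregation
R/campaign.R    scripted visit schedules and the end-to-end trial wrapper
exec/trapsim    command-line front end
```

See `vignettes/virtual-camera-trap.Rmd` for the modelling assumptions,
parameter choices and limitations.
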