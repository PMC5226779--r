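Package: trapsim
Title: Virtual Camera Trap with Confirmatory-Sensing Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free, fully testable re-creation of a customisable
    camera-trap platform. Simulates seeded arenas, animal tracks and rendered
    frames with known ground truth; models PIR and radar detection including
    their characteristic miss mechanisms (slow movers, rain-masked thermal
    contrast, small radar cross-sections, range limits); runs an event-driven
    trigger controller (motion captures with minimum spacing, scheduled
    time-lapse, active-hours gating, trigger latency, radar cross-referencing);
    classifies false-positive captures by background subtraction of a
    motion-activated frame against a recent time-lapse frame within a region
    of interest; embeds and extracts per-image EXIF metadata and CSV catalogs;
    and scores capture records against ground truth as true-positive,
    false-positive and false-negative counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    jpeg,
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
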