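Package: courtgaze
Title: Wearable Eye-Tracking Analysis for Live Team Sports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes recordings from a head-mounted eye tracker worn by
    referees and coaches during live team-sport games. Parses the device's
    CSV export family, fuses gaze, pupil-diameter and event streams onto
    the scene-camera frame timeline by nearest-timestamp matching, maps
    each gaze sample to a dynamically detected player bounding box
    (a dynamic area of interest), segments the player's upper clothing,
    classifies the jersey color into one of two teams in CIELAB space, and
    aggregates gaze-event counts and pupillometry per team and game phase.
    Includes Welch t-tests and a two-by-two mixed-design ANOVA for
    comparing observers and game phases, a full synthetic-recording
    generator with ground-truth sidecars, and mock detection/segmentation
    backends so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
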