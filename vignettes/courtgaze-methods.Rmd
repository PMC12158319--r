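---
title: "courtgaze: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{courtgaze: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what the test evidence does and does not
show. Commands below are illustrative; every empirical number mentioned is
computed by the test suite or `scripts/acceptance.R`, not asserted here.

## The measurement problem

A head-mounted eye tracker worn by a referee or coach during a live game
produces several asynchronous streams: a scene (point-of-view) camera
(1600 × 1200 px at 30 Hz on the reference device), gaze estimates and
3-D eye states at 200 Hz, and user/session events. Two questions drive the
analysis: *which team is the wearer looking at, and for how long*
(attention allocation), and *how large is the pupil while doing so*
(pupillometric proxy for cognitive load), broken down by game phase
(attack/defense) as labeled by expert annotators.

Static areas of interest do not exist on a court; the AOIs are the players
themselves. The pipeline therefore derives a *dynamic AOI* per frame from a
person detector, and resolves *which team* via the jersey color of the
player the gaze lands on. This works in any team sport where the two teams
wear distinctly different colors — preferably one light and one dark — and
within the sighting distances at which a jersey still covers enough pixels
to carry reliable color.

## Stream fusion

All tables are fused at the lowest camera rate, the 30 Hz scene clock. For
each scene frame the gaze sample and eye-state sample with minimal |Δt| are
attached, provided |Δt| ≤ tolerance. Design choices:

* **Nearest neighbor, not interpolation.** Pupil diameter is never
  interpolated across gaps; a frame without a sample inside the tolerance
  simply has a missing field. Missing data never drop frames: the output
  always has exactly one record per frame, which keeps run-length event
  logic well defined.
* **Tolerance** defaults to half the frame period (≈16.7 ms at 30 Hz), so
  a frame can only claim samples from its own frame interval. It is a
  configuration field (`alignment_config()`), because the right value is a
  property of the recording setup, not of the algorithm.
* **Ties** (a sample exactly equidistant to two frames, or two samples to
  one frame) resolve toward the earlier sample, for determinism.
* **Timestamps** are integer nanoseconds held in R doubles. Integers up to
  2^53 are exact; at Unix-epoch nanosecond scale (~1.7e18) the
  representable granularity is ~256 ns, five orders of magnitude below the
  tolerance, so alignment decisions are unaffected.
* **Normalization** divides pixel coordinates by the scene dimensions.
  Off-frame gaze is kept unclamped with `on_frame = FALSE` — useful for
  quality control — and excluded from AOI tests.

The alignment is verified against an exhaustive per-frame
argmin-over-all-samples oracle on randomized jittered instances up to 10^4
samples.

## Dynamic AOI and the perception contracts

Person detection and clothing segmentation are *contracts*, not baked-in
models: a detector backend maps a frame to boxes, a segmenter maps a crop
to a binary upper-clothing mask. Real pretrained networks plug in behind
these contracts; the shipped backends are deterministic mocks that read a
synthetic recording's ground-truth sidecar. This is deliberate: the
pipeline, not any particular set of weights, is the artifact, and mocks
make end-to-end tests *exact* rather than approximate. Detector
confidence thresholds and suppression settings are left to the backend.

Geometry conventions, chosen once and used everywhere: image origin
top-left, boxes are half-open integer pixel intervals, crops copy pixels.
A gaze hit selects the smallest-area containing box (ties: higher
confidence, then lower track id), on the assumption that the tightest box
is the most specific player when boxes nest or overlap. Track identities
are parsed but unused: every assignment is per-frame.

Per-frame failures (backend error, empty segmentation, unreadable frame)
downgrade that frame to `unknown`/`none` and never abort the run — a long
recording with a handful of bad frames must still produce a table.

## Jersey color and team assignment

The dominant color of the masked clothing crop is the **channel-wise
median** over mask-support pixels (zeros outside the mask never enter).
The median is robust to jersey numbers and trim; it is a deliberate,
documented stand-in — the classification contract is "match the known team
colors, else fall back to a light/dark rule", and the package implements
that contract with explicit, configurable pieces:

* Stage 1: convert the dominant color and the two palette references to
  CIELAB (D65); assign the nearer reference if its ΔE*ab ≤ 25.
* Stage 2 (fallback): classify by lightness — L* above 50 goes to the
  *lighter* reference's team, below to the darker, and a ±5 dead band
  returns `unknown`. Tying the rule to the lighter reference (rather than
  to a fixed label) is what makes classification exactly symmetric under
  swapping the palette.
* Observations supported by fewer than 25 pixels are `unknown`: at the far
  end of the usable range a jersey crop is tens of pixels, and medians
  over a handful of pixels are noise.

Palette loading enforces that the two references differ by more than twice
the match threshold, the formal version of "teams must wear distinctly
different colors". The default palette is white (light, team A) versus
navy (dark, team B). All thresholds live in the palette YAML.

## Gaze events and the feature table

"Number of gazes" is operationalized as **gaze events**: maximal runs of
consecutive frames assigned to the same team. Runs shorter than 2 frames
(≈67 ms) are discarded by default to suppress single-frame flicker from
detection noise; `min_event_frames = 1` gives strict mode. Raw frame
counts are reported alongside event counts, so an analysis preferring
either unit has both.

The feature table cells are (observed team × phase): gaze-event count
(events whose *start* frame falls in the phase), gaze-frame count, and the
mean and s.d. of pupil diameter pooled over the cell's frames (no
per-event pre-averaging; missing diameters excluded; a single diameter
reports s.d. 0, an empty cell reports missing). `total` rows sum counts
over teams — an invariant the tests assert exactly — and pool diameters.
Phases come from an annotation CSV (`start_ts`, `end_ts`, `phase`,
`attacking_team`), validated to be non-overlapping.

## Statistical layer

Two-sample t-tests compare a feature between two observers or phases.
Welch's variant is the default — observed cell s.d. for pupil summaries
can differ by an order of magnitude, where pooling is indefensible — with
the Student pooled test available. Significance marking uses p ≤ α,
α = 0.05.

The 2 × 2 mixed-design ANOVA (phase within subjects, coach between
subjects) uses the classical sums-of-squares decomposition: the between
effect is tested against subjects-within-groups, the within main effect
and interaction against the phase-by-subjects residual; with two groups
every effect is F(1, N − 2). The observation unit ("subject") is the
annotated clip. Degenerate inputs follow a documented convention: zero
effect SS reports F = 0, p = 1; positive effect SS over zero error SS
reports F = ∞, p = 0 with a warning. The implementation is hand-computed
from cell means and is cross-checked in the tests against the independent
`aov(value ~ coach * phase + Error(subject))` strata to 1e-8; the t
statistics are likewise checked against `stats::t.test`. No
multiple-testing correction is applied by default, matching common
practice in preliminary sports-psychology analyses; Holm correction can be
applied externally to the emitted p values.

## The synthetic generator: what it emulates, what it does not

`scene_script()` + `generate_session()` produce a complete recording:
painted players (skin band, jersey band, shorts band — the jersey band is
the geometric definition of "upper clothing" for the mock segmenter) over
a court-colored background, a scripted gaze trajectory (jersey centroids
plus Gaussian pixel noise, with optional sample dropout), a pupil series
(baseline 3.8 mm, +0.4 mm during defense, 0.05 mm sensor noise), all eight
export CSVs at the 30/200 Hz rate structure, phase annotations, and a
ground-truth sidecar with an independently recounted feature table.

Deliberate simplifications, and hence what passing tests do *not* show
about real data: no occlusion, no camera motion, no illumination change,
no photorealism; jerseys are solid colors; detection is perfect by
construction when the mock backend is used. The synthetic evidence
establishes that the *pipeline logic* is exact — alignment, AOI
resolution, mask arithmetic, color classification, aggregation — not that
any particular detector or segmenter is accurate on real footage. Noise
ladders (gaze noise 0–10 px) probe degradation of the logic, not of the
networks. Two rendering choices serve testability: the default synthetic
scene is 320 × 240 (the pipeline is resolution-agnostic, and hundreds of
frames render in seconds), and noise is drawn as standard normal scaled by
the requested s.d., so equal seeds share noise directions across a ladder
(common random numbers make the monotone-degradation property a property
of the system rather than of sampling luck).

For statistical calibration, `generate_null_and_effect_datasets()` draws
per-clip values with a Gaussian clip intercept (s.d. 0.5 mm) and residual
noise (s.d. 0.25 mm) around a 3.8 mm baseline. Between-clip variability
dominating the paired residual is the realistic regime for pupillometry
(different lighting and game moments across clips). Effect sizes are
expressed in units of the total s.d. (≈0.56 mm); a 1 s.d. phase shift at
8 clips per coach gives a noncentral-F within-effect power of ≈0.9999 by
the closed-form oracle, which the 500-replicate simulation confirms, and
the 2000-replicate null simulation shows the type-I rate at the nominal
0.05.

## Problem sizes and numerical notes

The test suite and acceptance script use 90–240-frame recordings, 100
randomized alignment instances (up to 10^4 samples), 100 random mask
pairs, a 4-level × 5-seed noise ladder at 60 frames, 2000 null and 500
effect replicates, and 50 cross-implementation comparisons; these sizes
give stable Monte-Carlo estimates while keeping a full run in minutes on
one CPU. Lab conversion uses `grDevices::convertColor`; the test oracle is
an independently hand-coded D65 transform, with agreement within ~0.3 ΔE
(white-point handling), far below the 25-unit decision gate. CSV output
uses explicit per-column formats (`%.0f` ns, `%.10f` reals) so identical
data yield identical bytes and round trips are lossless to 1e-9.

## Known limitations

* Two teams only; no illumination correction or white-balance estimation —
  a strongly color-casted venue would shift every jersey's ΔE.
* Single-device clocks are assumed coherent; no cross-device drift
  correction.
* Fixation/saccade/blink/IMU streams are parsed and retained but not
  analyzed; gaze events are run-length constructs, not fixations.
* Phase labels are external expert annotations; no automatic scene
  classification.
* The real-model adapters (detector/segmenter) are out of the tested
  surface by design; accuracy on real footage is bounded by those models,
  not by this package.
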