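# courtgaze

Wearable eye-tracking analysis for live team sports.

`courtgaze` processes recordings from a head-mounted eye tracker (the Pupil
Labs Neon export dialect) worn by referees and coaches during live games —
basketball being the motivating case. The scientific question behind the
pipeline: where do officials and coaches allocate visual attention (which
team, for how long), and how does their cognitive load — proxied by pupil
diameter — change between offensive and defensive game phases?

Laboratory eye-tracking uses static areas of interest (AOIs); on a live
court every salient region moves. The pipeline therefore builds *dynamic*
AOIs: a person detector proposes per-frame player bounding boxes, the gaze
point is tested against them, the hit player's upper clothing is segmented,
and the jersey color assigns the observation to a team.

## Pipeline

1. **Parse** the device's CSV export family — `world_timestamps.csv`,
   `gaze.csv`, `3d_eye_states.csv`, `events.csv`, plus the optional
   fixation/saccade/blink/IMU streams — into a validated session
   (`read_session()`).
2. **Align** gaze and pupil streams onto the scene-frame timeline at the
   lowest camera rate (30 Hz): each frame takes the sample with minimal
   |Δt|, within a tolerance of half a frame period (`align_streams()`);
   gaze coordinates are normalized to [0, 1] (`normalize_gaze()`).
3. **Detect and assign**: per frame, person boxes from a pluggable detector
   backend define the dynamic AOIs; an on-frame gaze point inside a box is
   a hit (`assign_gaze_to_box()`).
4. **Segment and classify**: the hit box is cropped, its upper clothing
   segmented to a binary mask, mask-multiplied (`apply_mask()`), and the
   channel-wise median color classified in CIELAB — nearest team reference
   within a ΔE*ab gate, then a light/dark lightness fallback, else
   `unknown` (`classify_team()`).
5. **Aggregate**: maximal same-team runs of frames become gaze events;
   counts and pupil-diameter statistics are tabulated per observed team ×
   game phase (`segment_gaze_events()`, `build_feature_table()`).
6. **Compare**: Welch/Student t-tests (`t_test_features()`) and a 2×2
   mixed-design ANOVA — game phase within subjects, coach between subjects
   (`mixed_anova_2x2()`), α = 0.05. For two groups all three effects are
   tested with F(1, N−2).

Pretrained detection/segmentation networks are *pluggable backends*; the
package ships deterministic mock backends driven by ground-truth sidecars,
plus a full synthetic-recording generator (`scene_script()`,
`generate_session()`), so everything above is testable offline and exactly.

## Worked example

```r
library(courtgaze)

# simulate a 90-frame game: 2 white (Team A) + 2 navy (Team B) players,
# gaze scripted onto jerseys, pupil +0.4 mm during defense
rec <- cmd_simulate(file.path(tempdir(), "rec"), seed = 7)

# full pipeline with the mock perception backends and default palette
out <- cmd_process(file.path(tempdir(), "rec"), file.path(tempdir(), "out"))
out$features
```

```
  observer_role  team   phase gaze_event_count gaze_frame_count pupil_mean   pupil_sd n_pupil
1      observer     A  attack                1               11   3.782296 0.03146571      11
2      observer     B  attack                2               27   3.803761 0.05961714      27
3      observer     A defense                1                7   4.229395 0.04888784       7
4      observer     B defense                1               15   4.196533 0.05919366      15
5      observer total  attack                3               38   3.797548 0.05350211      38
6      observer total defense                2               22   4.206989 0.05713339      22
```

Reading: during the attack phase the wearer produced 3 gaze events (38
frames) on players; pupil diameter averaged 3.80 mm in attack versus
4.21 mm in defense — recovering the scripted +0.4 mm defense shift. On this
noise-free recording the per-frame team labels and the whole table equal
the generator's ground-truth sidecar exactly.

Statistical layer on per-clip observations (two coaches × two phases):

```r
obs <- generate_null_and_effect_datasets(n_per_cell = 8, phase_shift_sd = 1,
                                         seed = 7)[[1]]
obs$measure <- "pupil_diameter"
cmd_stats(obs, file.path(tempdir(), "stats"))$anova
```

```
      effect         ss df_num df_den         ms   ms_error         F            p
1    between 3.66270944      1     14 3.66270944 0.50785772  7.212078 1.775239e-02
2     within 1.74442286      1     14 1.74442286 0.04193069 41.602531 1.522652e-05
3 interaction 0.05883149      1     14 0.05883149 0.04193069  1.403065 2.559310e-01
```

The injected within-phase shift is detected (F(1,14) = 41.6, p ≈ 1.5e-5).
No coach effect was scripted; the nominally significant between-groups F at
this particular seed is a textbook type-I illustration (the calibration
property in the test suite shows the long-run rate is 0.05).

A thin shell wrapper with `simulate` / `process` / `stats` / `demo`
subcommands ships at `system.file("cli", "courtgaze.R", package = "courtgaze")`.

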