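rec_box <- function(x0, y0, x1, y1, conf = 1, id = NA) {
  bounding_box(x0, y0, x1, y1, confidence = conf, track_id = id)
}
rec_at <- function(x, y, on = TRUE) {
  data.frame(frame_index = 0L, frame_timestamp = 0, gaze_px_x = x,
             gaze_px_y = y, on_frame = on)
}

test_that("gaze-in-box assignment picks the smallest containing box", {
  boxes <- rbind(rec_box(10, 10, 50, 90), rec_box(100, 10, 140, 90))
  hit <- assign_gaze_to_box(rec_at(30, 50), boxes)
  expect_true(hit$hit)
  expect_equal(hit$box$x_min, 10)

  miss <- assign_gaze_to_box(rec_at(70, 50), boxes)
  expect_false(miss$hit)
  expect_null(miss$box)

  # nested boxes: the inner (smaller-area) one wins; oracle by enumeration
  nested <- rbind(rec_box(10, 10, 90, 90, id = 1), rec_box(30, 30, 60, 60, id = 2))
  hit2 <- assign_gaze_to_box(rec_at(40, 40), nested)
  contains <- (40 >= nested$x_min & 40 < nested$x_max &
                 40 >= nested$y_min & 40 < nested$y_max)
  areas <- (nested$x_max - nested$x_min) * (nested$y_max - nested$y_min)
  expect_equal(hit2$box$track_id, nested$track_id[contains][
    which.min(areas[contains])])
  expect_equal(hit2$box$track_id, 2L)

  # equal areas: higher confidence, then lower track id
  tied <- rbind(rec_box(10, 10, 50, 50, conf = 0.6, id = 5),
                rec_box(0, 0, 40, 40, conf = 0.9, id = 9))
  expect_equal(assign_gaze_to_box(rec_at(20, 20), tied)$box$track_id, 9L)
  tied2 <- rbind(rec_box(10, 10, 50, 50, conf = 0.9, id = 5),
                 rec_box(0, 0, 40, 40, conf = 0.9, id = 9))
  expect_equal(assign_gaze_to_box(rec_at(20, 20), tied2)$box$track_id, 5L)

  # off-frame gaze never hits
  expect_false(assign_gaze_to_box(rec_at(30, 50, on = FALSE), boxes)$hit)
})

test_that("event segmentation is run-length encoding with a minimum length", {
  mk <- function(labels) data.frame(frame_index = seq_along(labels) - 1L,
                                    team = labels)
  ev <- segment_gaze_events(mk(c("A", "A", "A", "A", "B", "B", "B")),
                            min_event_frames = 1L)
  expect_equal(ev$team, c("A", "B"))
  expect_equal(ev$start_frame, c(0L, 4L))
  expect_equal(ev$end_frame, c(3L, 6L))
  expect_equal(ev$duration_frames, c(4L, 3L))

  # none breaks runs
  ev2 <- segment_gaze_events(mk(c("A", "none", "A")), min_event_frames = 1L)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$team, c("A", "A"))

  # runs shorter than the minimum are discarded
  ev3 <- segment_gaze_events(mk(c("A", "B", "B", "unknown", "A", "A")),
                             min_event_frames = 2L)
  expect_equal(ev3$team, c("B", "A"))

  # appending a trailing none-frame never changes the events
  set.seed(17)
  for (k in 1:20) {
    labels <- sample(c("A", "B", "none", "unknown"), 40, replace = TRUE)
    a <- segment_gaze_events(mk(labels), 2L)
    b <- segment_gaze_events(mk(c(labels, "none")), 2L)
    expect_equal(a, b)
    # independent RLE oracle
    r <- rle(labels)
    keep <- r$values %in% c("A", "B") & r$lengths >= 2L
    expect_equal(nrow(a), sum(keep))
    expect_equal(a$duration_frames, r$lengths[keep])
  }
})

test_that("feature table counts events and frames per cell with pupil stats", {
  # one attack phase, three 4-frame A-events separated by none, diameter 4.0
  labels <- rep(c("A", "A", "A", "A", "none"), 3)
  n <- length(labels)
  asg <- data.frame(frame_index = 0:(n - 1), frame_timestamp = (0:(n - 1)) * 1e7,
                    hit = labels != "none", team = labels,
                    pupil_diameter = 4.0)
  phases <- data.frame(start_ts = 0, end_ts = n * 1e7, phase = "attack",
                       attacking_team = "A")
  ev <- segment_gaze_events(asg, 2L)
  ft <- build_feature_table(asg, ev, phases)
  rowA <- ft[ft$team == "A" & ft$phase == "attack", ]
  expect_equal(rowA$gaze_event_count, 3L)
  expect_equal(rowA$gaze_frame_count, 12L)
  expect_equal(rowA$pupil_mean, 4.0)
  expect_equal(rowA$pupil_sd, 0.0)
  # empty cells report zero counts and missing pupil stats
  rowB <- ft[ft$team == "B" & ft$phase == "defense", ]
  expect_equal(rowB$gaze_event_count, 0L)
  expect_true(is.na(rowB$pupil_mean))
  # totals equal per-team sums
  for (ph in c("attack", "defense")) {
    tot <- ft[ft$team == "total" & ft$phase == ph, ]
    per <- ft[ft$team %in% c("A", "B") & ft$phase == ph, ]
    expect_equal(tot$gaze_event_count, sum(per$gaze_event_count))
    expect_equal(tot$gaze_frame_count, sum(per$gaze_frame_count))
  }
})

test_that("feature table equals a direct recount on a random label sequence", {
  set.seed(23)
  n <- 200L
  labels <- sample(c("A", "B", "none", "unknown"), n, replace = TRUE,
                   prob = c(0.35, 0.35, 0.2, 0.1))
  ts <- (0:(n - 1)) * 1e7
  dia <- round(rnorm(n, 4, 0.3), 3)
  dia[sample(n, 20)] <- NA
  asg <- data.frame(frame_index = 0:(n - 1), frame_timestamp = ts,
                    hit = labels %in% c("A", "B", "unknown"), team = labels,
                    pupil_diameter = dia)
  phases <- data.frame(start_ts = c(0, n / 2 * 1e7),
                       end_ts = c(n / 2 * 1e7, n * 1e7),
                       phase = c("attack", "defense"),
                       attacking_team = c("A", "B"))
  ev <- segment_gaze_events(asg, 2L)
  ft <- build_feature_table(asg, ev, phases)
  # oracle: filter the raw vectors directly
  phase_of <- ifelse(0:(n - 1) < n / 2, "attack", "defense")
  for (tm in c("A", "B")) for (ph in c("attack", "defense")) {
    row <- ft[ft$team == tm & ft$phase == ph, ]
    sel <- labels == tm & phase_of == ph
    expect_equal(row$gaze_frame_count, sum(sel))
    d <- dia[sel & !is.na(dia)]
    if (length(d)) expect_equal(row$pupil_mean, mean(d))
    r <- rle(labels)
    starts <- cumsum(r$lengths) - r$lengths + 1L
    expect_equal(row$gaze_event_count,
                 sum(r$values == tm & r$lengths >= 2L &
                       phase_of[starts] == ph))
  }
  # per-phase frame budget: team frames never exceed aligned frames
  for (ph in c("attack", "defense")) {
    per <- ft[ft$team %in% c("A", "B") & ft$phase == ph, ]
    expect_lte(sum(per$gaze_frame_count), sum(phase_of == ph))
  }
  # events always at least as rare as frames
  expect_true(all(ft$gaze_frame_count >= ft$gaze_event_count))
})

test_that("pipeline isolates per-frame failures without aborting", {
  rec <- make_recording(seed = 19, n_frames = 20L)
  s <- read_session(rec$dir, device = test_device())
  al <- align_streams(s)
  pal <- team_palette()
  # detector that never sees anyone -> all misses
  none_det <- list(name = "none", deterministic = TRUE,
                   detect = function(frame, idx) bounding_box(0, 0, 1, 1)[0, ])
  seg <- mock_segmenter(rec$dir)
  asg <- classify_frames(s, al, none_det, seg, pal)
  expect_true(all(!asg$hit))
  expect_true(all(asg$team == "none"))

  # segmenter failing on exactly one frame -> that frame unknown, others exact
  det <- mock_detector(rec$dir)
  seg_flaky <- list(name = "flaky", deterministic = TRUE,
                    segment = function(patch, idx, box) {
                      if (idx == 5L) stop("dropout")
                      mock_segmenter(rec$dir)$segment(patch, idx, box)
                    })
  expect_warning(asg2 <- classify_frames(s, al, det, seg_flaky, pal), "dropout")
  gt <- rec$ground_truth$labels
  affected <- asg2$frame_index == 5L & asg2$hit
  expect_true(all(asg2$team[!affected] == gt[!affected]))
  if (any(affected)) expect_equal(unique(asg2$team[affected]), "unknown")
})
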