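#' Script for a synthetic team-sport recording
#'
#' Describes everything needed to render a synthetic eye-tracking session:
#' the device geometry, two cohorts of uniformly colored players drifting
#' over a court-colored background, a gaze plan (which player, or the
#' background, the wearer looks at in each frame span), a phase plan
#' (attack/defense spans), and a pupil model (baseline diameter, additive
#' shift in the defense phase, and measurement noise). Everything downstream
#' of the seed is deterministic.
#'
#' Geometry defaults use a scaled-down 320 x 240 scene camera (same 30 Hz /
#' 200 Hz rate structure as the real device) so that hundreds of frames
#' render in seconds; the pipeline itself is resolution-agnostic.
#'
#' @param seed Integer seed; the script is a pure function of it.
#' @param n_frames Number of scene frames.
#' @param device A [device_spec()].
#' @param n_players_per_team Players rendered per team.
#' @param team_colors List with RGB triples (0..255) for teams `A` and `B`;
#'   defaults white (light) and navy (dark).
#' @param gaze_noise_px Gaussian noise s.d. added to the scripted gaze, in
#'   pixels. Noise draws are standard normal scaled by this value, so runs
#'   with the same seed share the same noise directions across noise levels.
#' @param dropout_rate Fraction of gaze samples dropped at random.
#' @param pupil List: `baseline` (mm), `phase_shift` (mm added during
#'   defense), `noise_sd` (mm).
#' @param background RGB triple of the court color.
#' @param t0_ns Timestamp of the first frame (nanoseconds).
#' @return Object of class `scene_script`.
#' @export
scene_script <- function(seed = 1L, n_frames = 90L,
                         device = device_spec(scene_width = 320,
                                              scene_height = 240),
                         n_players_per_team = 2L,
                         team_colors = list(A = c(255, 255, 255),
                                            B = c(0, 0, 128)),
                         gaze_noise_px = 0,
                         dropout_rate = 0,
                         pupil = list(baseline = 3.8, phase_shift = 0.4,
                                      noise_sd = 0.05),
                         background = c(190, 160, 120),
                         t0_ns = 1e9) {
  if (n_frames < 2L) cg_stop("scene_script: n_frames must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    cg_stop("scene_script: dropout_rate must be in [0, 1)")
  }
  w <- device$scene_width; h <- device$scene_height
  npl <- 2L * n_players_per_team
  pw <- max(12L, round(w / 9)); ph_ <- max(24L, round(h / 3))
  if (npl * (pw + 8L) > w - 40L) cg_stop("scene_script: too many players for frame width")

  script <- with_seed(seed, {
    # evenly spaced home columns, small seeded horizontal oscillation
    slot <- (w - 40L) / npl
    players <- data.frame(
      id = seq_len(npl),
      team = rep(c("A", "B"), each = n_players_per_team),
      x0 = round(30 + slot * (seq_len(npl) - 1L) + (slot - pw) / 2),
      y0 = round(h * 0.25) + sample(0:round(h * 0.15), npl, replace = TRUE),
      w = pw, h = ph_,
      amp = stats::runif(npl, 0, min(8, (slot - pw) / 2 - 1)),
      period = sample(40:80, npl, replace = TRUE),
      phase0 = stats::runif(npl, 0, 2 * pi))
    # gaze plan: spans of 6-14 frames, mostly on players
    plan <- list(); f <- 0L
    while (f < n_frames) {
      len <- sample(6:14, 1L)
      target <- if (stats::runif(1) < 0.8) sample(npl, 1L) else 0L
      plan[[length(plan) + 1L]] <- data.frame(
        start_frame = f, end_frame = min(f + len, n_frames) - 1L,
        target = target)
      f <- f + len
    }
    list(players = players, gaze_plan = do.call(rbind, plan))
  })

  half <- n_frames %/% 2L
  phase_plan <- data.frame(start_frame = c(0L, half),
                           end_frame_excl = c(half, n_frames),
                           phase = c("attack", "defense"),
                           attacking_team = c("A", "B"))

  structure(list(seed = seed, n_frames = n_frames, device = device,
                 players = script$players, gaze_plan = script$gaze_plan,
                 phase_plan = phase_plan,
                 team_colors = team_colors, gaze_noise_px = gaze_noise_px,
                 dropout_rate = dropout_rate, pupil = pupil,
                 background = round(background), t0_ns = t0_ns,
                 skin = c(224, 172, 138), shorts = c(45, 45, 45)),
            class = "scene_script")
}

# integer box of player p at frame t (half-open pixel intervals)
player_box_at <- function(script, p, t) {
  pl <- script$players[p, ]
  x0 <- round(pl$x0 + pl$amp * sin(2 * pi * t / pl$period + pl$phase0))
  x0 <- max(0L, min(x0, script$device$scene_width - pl$w))
  y0 <- pl$y0
  list(x_min = x0, y_min = y0, x_max = x0 + pl$w, y_max = y0 + pl$h)
}

# jersey (upper clothing) rectangle inside a player box
jersey_rect <- function(box) {
  hh <- box$y_max - box$y_min
  y_top <- box$y_min + round(0.15 * hh)
  y_bot <- box$y_min + round(0.55 * hh)
  list(x_min = box$x_min, y_min = y_top, x_max = box$x_max, y_max = y_bot)
}

render_frame <- function(script, t) {
  w <- script$device$scene_width; h <- script$device$scene_height
  img <- array(rep(script$background / 255, each = h * w), dim = c(h, w, 3))
  for (p in seq_len(nrow(script$players))) {
    box <- player_box_at(script, p, t)
    jr <- jersey_rect(box)
    col_team <- script$team_colors[[script$players$team[p]]] / 255
    fill <- function(b, col) {
      for (ch in 1:3) img[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max, ch] <<- col[ch]
    }
    fill(list(x_min = box$x_min, y_min = box$y_min, x_max = box$x_max,
              y_max = jr$y_min), script$skin / 255)
    fill(jr, col_team)
    fill(list(x_min = box$x_min, y_min = jr$y_max, x_max = box$x_max,
              y_max = box$y_max), script$shorts / 255)
  }
  img
}

#' Generate a complete synthetic recording with ground truth
#'
#' Renders the scripted scene to a recording directory in the exact layout
#' [read_session()] parses: PNG scene frames, the eight-stream CSV export
#' family (gaze and pupil at the eye rate, world timestamps at the scene
#' rate), a phase-annotation CSV, a ground-truth sidecar
#' (`sidecar.json`: true boxes, jersey rectangles and gazed team per frame)
#' and a ground-truth feature table computed by direct recount of the true
#' labels. Fully reproducible from the script's seed.
#'
#' @param script A [scene_script()].
#' @param dir Output recording directory.
#' @param min_event_frames Event rule used for the ground-truth feature
#'   table (must match the analysis setting to compare tables).
#' @return List with `dir` and `ground_truth` (frames, per-frame labels,
#'   feature table, phase table).
#' @export
generate_session <- function(script, dir, min_event_frames = 2L) {
  stopifnot(inherits(script, "scene_script"))
  dev <- script$device
  n <- script$n_frames
  world_ts <- script$t0_ns + round((seq_len(n) - 1L) * 1e9 / dev$scene_rate)
  m <- round(n * dev$eye_rate / dev$scene_rate)
  eye_ts <- script$t0_ns + round((seq_len(m) - 1L) * 1e9 / dev$eye_rate)

  # per-frame plan target and phase
  target_of <- integer(n)
  for (i in seq_len(nrow(script$gaze_plan))) {
    g <- script$gaze_plan[i, ]
    target_of[(g$start_frame:g$end_frame) + 1L] <- g$target
  }
  phase_ts <- data.frame(
    start_ts = world_ts[script$phase_plan$start_frame + 1L],
    end_ts = script$t0_ns +
      round(script$phase_plan$end_frame_excl * 1e9 / dev$scene_rate),
    phase = script$phase_plan$phase,
    attacking_team = script$phase_plan$attacking_team)
  frame_phase <- phase_of_timestamps(world_ts, phase_ts)

  sim <- with_seed(script$seed + 1L, {
    frame_of_sample <- nearest_index(eye_ts, world_ts)
    # scripted gaze: jersey centroid of the target, corner point for background
    gx <- numeric(m); gy <- numeric(m)
    for (s in seq_len(m)) {
      f <- frame_of_sample[[s]]
      tg <- target_of[[f]]
      if (tg == 0L) {
        gx[s] <- 8; gy[s] <- 8
      } else {
        jr <- jersey_rect(player_box_at(script, tg, f - 1L))
        gx[s] <- (jr$x_min + jr$x_max) / 2
        gy[s] <- (jr$y_min + jr$y_max) / 2
      }
    }
    # scale-invariant noise draws: same seed => same directions at any sd
    noise <- matrix(stats::rnorm(2L * m), ncol = 2L)
    gx <- gx + noise[, 1] * script$gaze_noise_px
    gy <- gy + noise[, 2] * script$gaze_noise_px
    sample_phase <- frame_phase[frame_of_sample]
    pupil <- script$pupil$baseline +
      script$pupil$phase_shift * (sample_phase == "defense") +
      stats::rnorm(m) * script$pupil$noise_sd
    keep <- stats::runif(m) >= script$dropout_rate
    list(gx = gx, gy = gy, pupil = pupil, keep = keep)
  })

  gaze <- data.frame(timestamp = eye_ts[sim$keep],
                     gaze_x = sim$gx[sim$keep], gaze_y = sim$gy[sim$keep],
                     confidence = 1)
  eye_states <- data.frame(timestamp = eye_ts, pupil_left = NA_real_,
                           pupil_right = NA_real_, pupil_diameter = sim$pupil)
  events <- data.frame(
    timestamp = c(world_ts[[1L]], phase_ts$start_ts,
                  world_ts[[n]]),
    name = c("recording.begin", paste0("phase.", phase_ts$phase),
             "recording.end"))
  events <- events[!duplicated(events$timestamp), ]

  # small plausible optional streams (parsed, never analyzed)
  ix <- function(i) world_ts[[pmin(i, n)]]
  fixations <- data.frame(start_timestamp = c(ix(2L), ix(10L)),
                          end_timestamp = c(ix(5L), ix(14L)),
                          x = c(100, 150), y = c(100, 120))
  saccades <- data.frame(start_timestamp = c(ix(6L), ix(15L)),
                         end_timestamp = c(ix(7L), ix(16L)),
                         amplitude = c(3.2, 5.1))
  blinks <- data.frame(start_timestamp = ix(20L),
                       end_timestamp = ix(21L))
  imu <- data.frame(timestamp = world_ts[1:5], gyro_x = 0, gyro_y = 0,
                    gyro_z = 0)

  # write the recording ------------------------------------------------------
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames_data <- lapply(seq_len(n) - 1L, function(t) render_frame(script, t))
  session <- structure(list(device = dev,
                            world = data.frame(frame_index = seq_len(n) - 1L,
                                               timestamp = world_ts),
                            gaze = gaze, eye_states = eye_states,
                            events = events, fixations = fixations,
                            saccades = saccades, blinks = blinks, imu = imu,
                            frame_files = character(0),
                            frames_data = frames_data, source_dir = dir),
                       class = "neon_session")
  write_session(session, dir)
  write_phases(phase_ts, file.path(dir, "phases.csv"))

  # ground truth --------------------------------------------------------------
  labels <- ifelse(target_of == 0L, "none",
                   script$players$team[pmax(target_of, 1L)])
  gt_frames <- lapply(seq_len(n), function(i) {
    t <- i - 1L
    boxes <- lapply(seq_len(nrow(script$players)), function(p) {
      b <- player_box_at(script, p, t)
      b$confidence <- 1
      b$team <- script$players$team[p]
      b
    })
    jerseys <- lapply(seq_len(nrow(script$players)), function(p) {
      j <- jersey_rect(player_box_at(script, p, t))
      j$team <- script$players$team[p]
      j
    })
    list(frame_index = t, boxes = boxes, jerseys = jerseys,
         gazed_team = labels[[i]], target = target_of[[i]])
  })
  gt_features <- ground_truth_features(labels, frame_phase, eye_ts, sim$pupil,
                                       world_ts, min_event_frames)
  ground_truth <- list(frames = gt_frames, labels = labels,
                       frame_phase = frame_phase,
                       feature_table = gt_features, phases = phase_ts)
  jsonlite::write_json(list(frames = gt_frames, labels = labels),
                       file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  write_feature_table(gt_features, file.path(dir, "ground_truth_features.csv"))
  list(dir = dir, ground_truth = ground_truth)
}

# Direct recount of the true per-frame labels into the feature-table cells,
# written independently of the pipeline's aggregation path.
ground_truth_features <- function(labels, frame_phase, eye_ts, pupil,
                                  world_ts, min_event_frames) {
  n <- length(labels)
  # per-frame pupil: value of the temporally nearest eye sample
  dia <- vapply(seq_len(n), function(i) {
    pupil[[which.min(abs(eye_ts - world_ts[[i]]))]]
  }, numeric(1))
  # run lengths of identical team labels
  r <- rle(labels)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- list()
  for (ph in c("attack", "defense")) {
    for (tm in c("A", "B")) {
      nev <- 0L
      for (k in seq_along(r$values)) {
        if (r$values[[k]] == tm && r$lengths[[k]] >= min_event_frames &&
            frame_phase[[starts[[k]]]] == ph) {
          nev <- nev + 1L
        }
      }
      sel <- labels == tm & frame_phase == ph
      d <- dia[sel]
      rows[[length(rows) + 1L]] <- data.frame(
        observer_role = "observer", team = tm, phase = ph,
        gaze_event_count = nev, gaze_frame_count = sum(sel),
        pupil_mean = if (length(d)) mean(d) else NA_real_,
        pupil_sd = if (length(d) > 1L) stats::sd(d) else
          if (length(d) == 1L) 0 else NA_real_,
        n_pupil = length(d))
    }
  }
  per_team <- do.call(rbind, rows[c(1, 2, 3, 4)])
  # reorder to match build_feature_table (A,B within phase; then totals)
  per_team <- per_team[order(per_team$phase, per_team$team), ]
  totals <- do.call(rbind, lapply(c("attack", "defense"), function(ph) {
    sel <- labels %in% c("A", "B") & frame_phase == ph
    d <- dia[sel]
    data.frame(observer_role = "observer", team = "total", phase = ph,
               gaze_event_count = sum(per_team$gaze_event_count[
                 per_team$phase == ph]),
               gaze_frame_count = sum(sel),
               pupil_mean = if (length(d)) mean(d) else NA_real_,
               pupil_sd = if (length(d) > 1L) stats::sd(d) else
                 if (length(d) == 1L) 0 else NA_real_,
               n_pupil = length(d))
  }))
  out <- rbind(per_team, totals)
  rownames(out) <- NULL
  class(out) <- c("feature_table", class(out))
  out
}

#' Draw long-format observation sets for statistical calibration
#'
#' Simulates per-clip measurements under the mixed 2x2 design: two coach
#' groups (between), two game phases (within), a Gaussian random clip
#' intercept, and Gaussian residual noise. Effect sizes are expressed in
#' units of the total observation standard deviation
#' `sqrt(subject_sd^2 + noise_sd^2)`; an effect of zero reproduces the null
#' draws exactly under the same seed.
#'
#' @param n_per_cell Subjects (clips) per coach group.
#' @param n_replicates Number of independent datasets to draw.
#' @param phase_shift_sd Within-subject phase effect (defense minus attack),
#'   in total-s.d. units.
#' @param coach_shift_sd Between-group effect, in total-s.d. units.
#' @param interaction_sd Phase-by-coach interaction, in total-s.d. units.
#' @param baseline Grand mean (mm, for pupil-like measurements).
#' @param subject_sd Random clip-intercept s.d. (between-clip variability).
#' @param noise_sd Residual s.d. within clip and phase.
#' @param seed Integer seed.
#' @return List of `n_replicates` long data frames with columns
#'   `subject_id`, `coach`, `phase`, `value`.
#' @export
generate_null_and_effect_datasets <- function(n_per_cell = 8L,
                                              n_replicates = 1L,
                                              phase_shift_sd = 0,
                                              coach_shift_sd = 0,
                                              interaction_sd = 0,
                                              baseline = 3.8,
                                              subject_sd = 0.5,
                                              noise_sd = 0.25,
                                              seed = 1L) {
  if (n_per_cell < 2L) cg_stop("need >= 2 subjects per cell")
  total_sd <- sqrt(subject_sd^2 + noise_sd^2)
  phase_eff <- phase_shift_sd * total_sd
  coach_eff <- coach_shift_sd * total_sd
  inter_eff <- interaction_sd * total_sd
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      N <- 2L * n_per_cell
      coach <- rep(c("A", "B"), each = n_per_cell)
      b_i <- stats::rnorm(N) * subject_sd
      rows <- lapply(seq_len(N), function(i) {
        eps <- stats::rnorm(2L) * noise_sd
        is_b <- coach[[i]] == "B"
        data.frame(
          subject_id = i, coach = coach[[i]],
          phase = c("attack", "defense"),
          value = baseline + b_i[[i]] + coach_eff * is_b +
            c(0, phase_eff) + c(0, inter_eff * is_b) + eps)
      })
      do.call(rbind, rows)
    })
  })
}
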