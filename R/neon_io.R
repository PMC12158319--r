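#' Column-name dialect for the eye-tracker CSV export family
#'
#' Vendor export headers drift across software versions, so every logical
#' field is looked up through a list of accepted column names. The default
#' accepts both the compact dialect written by [write_session()]
#' (`timestamp`, `x`, `y`, `confidence`, `diameter`, ...) and the cloud-style
#' headers (`timestamp [ns]`, `gaze x [px]`, `pupil diameter left [mm]`, ...).
#'
#' @return A nested list: stream -> logical field -> character vector of
#'   accepted column headers, in priority order.
#' @export
neon_dialect <- function() {
  list(
    world_timestamps = list(
      timestamp = c("timestamp", "timestamp [ns]", "world_timestamp")
    ),
    gaze = list(
      timestamp  = c("timestamp", "timestamp [ns]"),
      x          = c("x", "gaze x [px]", "gaze_x"),
      y          = c("y", "gaze y [px]", "gaze_y"),
      confidence = c("confidence", "worn")
    ),
    eye_states = list(
      timestamp      = c("timestamp", "timestamp [ns]"),
      diameter       = c("diameter", "pupil diameter [mm]"),
      diameter_left  = c("diameter_left", "pupil diameter left [mm]"),
      diameter_right = c("diameter_right", "pupil diameter right [mm]")
    ),
    events = list(
      timestamp = c("timestamp", "timestamp [ns]"),
      name      = c("name", "event", "label")
    )
  )
}

MANDATORY_FILES <- c("world_timestamps.csv", "gaze.csv",
                     "3d_eye_states.csv", "events.csv")
OPTIONAL_FILES <- c("fixations.csv", "saccades.csv", "blinks.csv", "imu.csv")

# read a CSV with all cells as character; fatal on absent file
read_raw_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, colClasses = "character",
                  stringsAsFactors = FALSE)
}

# pick the first present candidate column; NULL if none
pick_col <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit) == 0L) return(NULL)
  df[[hit[[1L]]]]
}

# parse a character column to numeric; fatal naming file and first bad row
parse_num <- function(x, file, col) {
  x[x == ""] <- NA_character_
  suppressWarnings(v <- as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad) > 0L) {
    cg_stop("unparseable value in %s, column '%s', data row %d: '%s'",
            file, col, bad[[1L]], x[[bad[[1L]]]])
  }
  v
}

# Timestamps are integers in nanoseconds internally. Inputs in float seconds
# are detected by magnitude (a 30 Hz session expressed in ns exceeds 1e7
# within a second; seconds-scale values stay far below) and converted.
to_ns <- function(ts, file) {
  if (length(ts) > 0L && max(ts, na.rm = TRUE) < 1e7) {
    cg_log(sprintf("%s: timestamps look like seconds; converting to ns", file))
    ts <- ts * 1e9
  }
  round(ts)
}

check_strictly_increasing <- function(ts, file) {
  if (length(ts) > 1L) {
    bad <- which(diff(ts) <= 0)
    if (length(bad) > 0L) {
      cg_stop("non-monotonic timestamps in %s: row %d does not increase over row %d",
              file, bad[[1L]] + 1L, bad[[1L]])
    }
  }
  invisible(ts)
}

#' Read an eye-tracking recording directory into a session object
#'
#' Parses the CSV export family of the recording device into a validated
#' session: the scene-frame timeline (`world_timestamps.csv`), gaze samples
#' with confidence (`gaze.csv`), pupil diameters (`3d_eye_states.csv`),
#' session events (`events.csv`), and the optional fixation, saccade, blink
#' and IMU streams (parsed and retained, not analyzed). Scene frames are
#' resolved from a directory of ordered image files.
#'
#' When both per-eye pupil diameters are present they are averaged into a
#' single `pupil_diameter` per sample.
#'
#' @param recording_dir Path to the recording directory.
#' @param device A [device_spec()].
#' @param dialect Column-name dialect, see [neon_dialect()].
#' @param frames_subdir Name of the sub-directory holding scene frames as
#'   PNG (or JPEG) files in lexicographic frame order.
#' @param require_frames If `TRUE` (default) a resolvable frame source is
#'   mandatory; set `FALSE` for table-only work.
#' @return An object of class `neon_session`.
#' @export
read_session <- function(recording_dir, device = device_spec(),
                         dialect = neon_dialect(),
                         frames_subdir = "frames",
                         require_frames = TRUE) {
  if (!dir.exists(recording_dir)) {
    cg_stop("recording directory not found: %s", recording_dir)
  }
  for (f in MANDATORY_FILES) {
    if (!file.exists(file.path(recording_dir, f))) {
      cg_stop("missing mandatory file: %s", f)
    }
  }

  # world timeline ---------------------------------------------------------
  raw <- read_raw_csv(file.path(recording_dir, "world_timestamps.csv"))
  ts <- pick_col(raw, dialect$world_timestamps$timestamp)
  if (is.null(ts)) cg_stop("world_timestamps.csv: no timestamp column found")
  ts <- to_ns(parse_num(ts, "world_timestamps.csv", "timestamp"),
              "world_timestamps.csv")
  check_strictly_increasing(ts, "world_timestamps.csv")
  world <- data.frame(frame_index = seq_along(ts) - 1L, timestamp = ts)

  # gaze -------------------------------------------------------------------
  raw <- read_raw_csv(file.path(recording_dir, "gaze.csv"))
  g_ts <- pick_col(raw, dialect$gaze$timestamp)
  g_x <- pick_col(raw, dialect$gaze$x)
  g_y <- pick_col(raw, dialect$gaze$y)
  if (is.null(g_ts) || is.null(g_x) || is.null(g_y)) {
    cg_stop("gaze.csv: required columns (timestamp, x, y) not found")
  }
  g_conf <- pick_col(raw, dialect$gaze$confidence)
  gaze <- data.frame(
    timestamp = to_ns(parse_num(g_ts, "gaze.csv", "timestamp"), "gaze.csv"),
    gaze_x = parse_num(g_x, "gaze.csv", "x"),
    gaze_y = parse_num(g_y, "gaze.csv", "y"),
    confidence = if (is.null(g_conf)) rep(NA_real_, nrow(raw)) else
      parse_num(g_conf, "gaze.csv", "confidence")
  )
  check_strictly_increasing(gaze$timestamp, "gaze.csv")
  bad_conf <- which(!is.na(gaze$confidence) &
                      (gaze$confidence < 0 | gaze$confidence > 1))
  if (length(bad_conf) > 0L) {
    cg_stop("gaze.csv: confidence outside [0,1] at data row %d", bad_conf[[1L]])
  }

  # pupil / eye states ------------------------------------------------------
  raw <- read_raw_csv(file.path(recording_dir, "3d_eye_states.csv"))
  e_ts <- pick_col(raw, dialect$eye_states$timestamp)
  if (is.null(e_ts)) cg_stop("3d_eye_states.csv: no timestamp column found")
  e_d <- pick_col(raw, dialect$eye_states$diameter)
  e_l <- pick_col(raw, dialect$eye_states$diameter_left)
  e_r <- pick_col(raw, dialect$eye_states$diameter_right)
  if (is.null(e_d) && is.null(e_l) && is.null(e_r)) {
    cg_stop("3d_eye_states.csv: no pupil diameter column found")
  }
  n <- nrow(raw)
  left  <- if (is.null(e_l)) rep(NA_real_, n) else parse_num(e_l, "3d_eye_states.csv", "diameter_left")
  right <- if (is.null(e_r)) rep(NA_real_, n) else parse_num(e_r, "3d_eye_states.csv", "diameter_right")
  single <- if (is.null(e_d)) rep(NA_real_, n) else parse_num(e_d, "3d_eye_states.csv", "diameter")
  both <- rowMeans(cbind(left, right), na.rm = TRUE)
  both[is.nan(both)] <- NA_real_
  diameter <- ifelse(is.na(single), both, single)
  if (any(!is.na(diameter) & diameter <= 0)) {
    cg_stop("3d_eye_states.csv: pupil diameter must be > 0 when present (row %d)",
            which(!is.na(diameter) & diameter <= 0)[[1L]])
  }
  eye_states <- data.frame(
    timestamp = to_ns(parse_num(e_ts, "3d_eye_states.csv", "timestamp"),
                      "3d_eye_states.csv"),
    pupil_left = left, pupil_right = right, pupil_diameter = diameter)
  check_strictly_increasing(eye_states$timestamp, "3d_eye_states.csv")

  # events -------------------------------------------------------------------
  raw <- read_raw_csv(file.path(recording_dir, "events.csv"))
  ev_ts <- pick_col(raw, dialect$events$timestamp)
  ev_nm <- pick_col(raw, dialect$events$name)
  if (is.null(ev_ts) || is.null(ev_nm)) {
    cg_stop("events.csv: required columns (timestamp, name) not found")
  }
  if (any(!is.na(ev_nm) & ev_nm == "")) {
    cg_stop("events.csv: empty event name at data row %d", which(ev_nm == "")[[1L]])
  }
  events <- data.frame(
    timestamp = to_ns(parse_num(ev_ts, "events.csv", "timestamp"), "events.csv"),
    name = as.character(ev_nm))

  # optional streams: retained verbatim, unanalyzed --------------------------
  optional <- list()
  for (f in OPTIONAL_FILES) {
    nm <- sub("\\.csv$", "", f)
    p <- file.path(recording_dir, f)
    if (file.exists(p)) {
      optional[[nm]] <- utils::read.csv(p, check.names = FALSE,
                                        stringsAsFactors = FALSE)
    } else {
      cg_log(sprintf("optional stream %s absent; continuing with empty table", f))
      optional[[nm]] <- data.frame()
    }
  }

  # frames --------------------------------------------------------------------
  frame_files <- character(0)
  fdir <- file.path(recording_dir, frames_subdir)
  if (dir.exists(fdir)) {
    frame_files <- sort(list.files(fdir, pattern = "\\.(png|jpg|jpeg)$",
                                   ignore.case = TRUE, full.names = TRUE))
  }
  if (require_frames) {
    if (length(frame_files) == 0L) {
      cg_stop("no scene frames found under %s", fdir)
    }
    if (length(frame_files) != nrow(world)) {
      cg_stop("frame count (%d) does not match world_timestamps rows (%d)",
              length(frame_files), nrow(world))
    }
  }

  structure(list(device = device, world = world, gaze = gaze,
                 eye_states = eye_states, events = events,
                 fixations = optional$fixations, saccades = optional$saccades,
                 blinks = optional$blinks, imu = optional$imu,
                 frame_files = frame_files, source_dir = recording_dir),
            class = "neon_session")
}

#' @export
print.neon_session <- function(x, ...) {
  cat(sprintf(paste0("<neon_session> %d frames, %d gaze samples, %d eye states,",
                     " %d events (%s)\n"),
              nrow(x$world), nrow(x$gaze), nrow(x$eye_states), nrow(x$events),
              x$source_dir))
  invisible(x)
}

#' Fetch one scene frame of a session
#'
#' @param session A `neon_session`.
#' @param frame_index Zero-based frame index.
#' @return Numeric array (height x width x 3) in `[0, 1]`, with the frame
#'   index attached as attribute `frame_index`.
#' @export
get_frame <- function(session, frame_index) {
  i <- frame_index + 1L
  if (length(session$frame_files) == 0L) cg_stop("session has no frame source")
  if (i < 1L || i > length(session$frame_files)) {
    cg_stop("frame_index %d out of range [0, %d]",
            frame_index, length(session$frame_files) - 1L)
  }
  img <- png::readPNG(session$frame_files[[i]])
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  attr(img, "frame_index") <- frame_index
  img
}

#' Write a session back to disk in the compact CSV dialect
#'
#' Emits the full export family (all eight CSV streams) plus the scene
#' frames as PNG files, producing a directory that [read_session()] parses
#' back into an identical session. Used by the synthetic generator and
#' useful for fixture construction.
#'
#' @param session A `neon_session`. `frames` entries may also be supplied as
#'   in-memory arrays via `session$frames_data` (list of height x width x 3
#'   arrays) when `frame_files` is empty.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_formatted(data.frame(timestamp = session$world$timestamp),
                      file.path(dir, "world_timestamps.csv"),
                      list(timestamp = FMT_TS))
  write_csv_formatted(session$gaze[, c("timestamp", "gaze_x", "gaze_y", "confidence")] |>
                        stats::setNames(c("timestamp", "x", "y", "confidence")),
                      file.path(dir, "gaze.csv"),
                      list(timestamp = FMT_TS, x = FMT_REAL, y = FMT_REAL,
                           confidence = "%.6f"))
  write_csv_formatted(data.frame(timestamp = session$eye_states$timestamp,
                                 diameter = session$eye_states$pupil_diameter),
                      file.path(dir, "3d_eye_states.csv"),
                      list(timestamp = FMT_TS, diameter = FMT_REAL))
  write_csv_formatted(session$events, file.path(dir, "events.csv"),
                      list(timestamp = FMT_TS, name = "s"))
  for (nm in c("fixations", "saccades", "blinks", "imu")) {
    df <- session[[nm]]
    if (is.null(df) || nrow(df) == 0L) {
      df <- switch(nm,
        fixations = data.frame(start_timestamp = numeric(0), end_timestamp = numeric(0),
                               x = numeric(0), y = numeric(0)),
        saccades = data.frame(start_timestamp = numeric(0), end_timestamp = numeric(0),
                              amplitude = numeric(0)),
        blinks = data.frame(start_timestamp = numeric(0), end_timestamp = numeric(0)),
        imu = data.frame(timestamp = numeric(0), gyro_x = numeric(0),
                         gyro_y = numeric(0), gyro_z = numeric(0)))
    }
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE,
                     quote = FALSE)
  }
  fdir <- file.path(dir, "frames")
  dir.create(fdir, showWarnings = FALSE)
  if (length(session$frame_files) > 0L) {
    file.copy(session$frame_files,
              file.path(fdir, sprintf("frame_%06d.png",
                                      seq_along(session$frame_files) - 1L)))
  } else if (!is.null(session$frames_data)) {
    for (i in seq_along(session$frames_data)) {
      png::writePNG(session$frames_data[[i]],
                    file.path(fdir, sprintf("frame_%06d.png", i - 1L)))
    }
  }
  invisible(dir)
}

#' Write pipeline outputs: per-frame assignments, feature table, manifest
#'
#' @param assignments Data frame of per-frame team assignments as produced
#'   by [classify_frames()].
#' @param features A feature table from [build_feature_table()].
#' @param out_dir Output directory (created if needed).
#' @param extra_files Optional character vector of additional files (e.g.
#'   annotated frames) already under `out_dir`, to list in the manifest.
#' @return The manifest (named list), invisibly; written as `manifest.json`.
#' @export
write_outputs <- function(assignments, features, out_dir,
                          extra_files = character(0)) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) cg_stop("cannot create output directory: %s", out_dir)
  a_path <- file.path(out_dir, "assignments.csv")
  write_csv_formatted(
    assignments[, c("frame_index", "frame_timestamp", "hit", "team",
                    "box_x_min", "box_y_min", "box_x_max", "box_y_max",
                    "dominant_r", "dominant_g", "dominant_b", "n_pixels",
                    "pupil_diameter")],
    a_path,
    list(frame_index = "%d", frame_timestamp = FMT_TS, hit = "s", team = "s",
         box_x_min = "%.0f", box_y_min = "%.0f", box_x_max = "%.0f",
         box_y_max = "%.0f", dominant_r = "%.4f", dominant_g = "%.4f",
         dominant_b = "%.4f", n_pixels = "%.0f", pupil_diameter = FMT_REAL))
  f_path <- file.path(out_dir, "feature_table.csv")
  write_feature_table(features, f_path)
  manifest <- list(
    files = c("assignments.csv", "feature_table.csv", extra_files),
    n_assignments = nrow(assignments),
    n_feature_rows = nrow(features))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read back a per-frame assignment CSV written by [write_outputs()]
#' @param path Path to `assignments.csv`.
#' @return Data frame with the documented columns.
#' @export
read_assignments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$hit <- as.logical(df$hit)
  df
}
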