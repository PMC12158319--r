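#' Temporal-alignment configuration
#'
#' Streams are fused at the lowest camera rate (the scene camera, 30 Hz by
#' default): each scene frame takes the gaze and eye-state sample nearest in
#' time, provided the distance does not exceed `tolerance_ns`. The default
#' tolerance is half the scene frame period (about 16.7 ms at 30 Hz), so a
#' frame only ever matches samples from its own frame interval.
#'
#' @param rate Scene sampling rate in Hz.
#' @param tolerance_ns Matching tolerance in nanoseconds; default half the
#'   frame period.
#' @return An object of class `alignment_config`.
#' @export
alignment_config <- function(rate = 30, tolerance_ns = NULL) {
  if (rate <= 0) cg_stop("alignment_config: rate must be > 0")
  tolerance_ns <- tolerance_ns %||% (0.5 * 1e9 / rate)
  if (!is.finite(tolerance_ns) || tolerance_ns <= 0) {
    cg_stop("alignment_config: tolerance must be > 0")
  }
  structure(list(rate = rate, tolerance_ns = tolerance_ns),
            class = "alignment_config")
}

#' Normalize gaze pixel coordinates to the unit square
#'
#' Maps scene-camera pixel coordinates to a normalized space between 0 and 1
#' by dividing by the scene dimensions. Points outside the frame are
#' returned unclamped with `on_frame = FALSE` so quality control can see
#' them; downstream area-of-interest tests ignore them.
#'
#' @param x,y Gaze position in pixels (vectorized).
#' @param device A [device_spec()].
#' @return Data frame with `norm_x`, `norm_y`, `on_frame`.
#' @examples
#' normalize_gaze(800, 600, device_spec())  # frame midpoint -> (0.5, 0.5)
#' @export
normalize_gaze <- function(x, y, device) {
  nx <- x / device$scene_width
  ny <- y / device$scene_height
  on <- is.finite(nx) & is.finite(ny) &
    nx >= 0 & nx <= 1 & ny >= 0 & ny <= 1
  data.frame(norm_x = nx, norm_y = ny, on_frame = on)
}

#' Fuse gaze and pupil streams onto the scene-frame timeline
#'
#' Produces exactly one record per scene frame. Each frame is matched to the
#' gaze sample and the eye-state sample with minimal absolute timestamp
#' difference; a match farther than the tolerance leaves that field missing
#' (the frame itself is never dropped). Ties in temporal distance are broken
#' toward the earlier sample.
#'
#' @param session A `neon_session`.
#' @param cfg An [alignment_config()].
#' @return Data frame with one row per frame: `frame_index`,
#'   `frame_timestamp`, raw and normalized gaze, `confidence`, `on_frame`,
#'   `pupil_diameter`, and the matched time offsets `gaze_dt_ns`,
#'   `pupil_dt_ns` (NA where unmatched).
#' @export
align_streams <- function(session, cfg = alignment_config()) {
  if (nrow(session$world) == 0L) cg_stop("align_streams: empty world timeline")
  ft <- session$world$timestamp
  n <- length(ft)
  out <- data.frame(
    frame_index = session$world$frame_index,
    frame_timestamp = ft,
    gaze_px_x = NA_real_, gaze_px_y = NA_real_,
    gaze_norm_x = NA_real_, gaze_norm_y = NA_real_,
    confidence = NA_real_, on_frame = FALSE,
    pupil_diameter = NA_real_,
    gaze_dt_ns = NA_real_, pupil_dt_ns = NA_real_)

  if (nrow(session$gaze) > 0L) {
    gi <- nearest_index(ft, session$gaze$timestamp)
    dt <- session$gaze$timestamp[gi] - ft
    ok <- abs(dt) <= cfg$tolerance_ns
    if (any(!ok)) {
      cg_log(sprintf("align_streams: %d frame(s) without a gaze sample within tolerance",
                     sum(!ok)))
    }
    out$gaze_px_x[ok] <- session$gaze$gaze_x[gi[ok]]
    out$gaze_px_y[ok] <- session$gaze$gaze_y[gi[ok]]
    out$confidence[ok] <- session$gaze$confidence[gi[ok]]
    out$gaze_dt_ns[ok] <- dt[ok]
    nz <- normalize_gaze(out$gaze_px_x, out$gaze_px_y, session$device)
    out$gaze_norm_x <- nz$norm_x
    out$gaze_norm_y <- nz$norm_y
    out$on_frame <- nz$on_frame & ok
  } else {
    cg_log("align_streams: gaze stream empty; all frames unmatched")
  }

  if (nrow(session$eye_states) > 0L) {
    valid <- !is.na(session$eye_states$pupil_diameter)
    ets <- session$eye_states$timestamp[valid]
    ed <- session$eye_states$pupil_diameter[valid]
    if (length(ets) > 0L) {
      ei <- nearest_index(ft, ets)
      dt <- ets[ei] - ft
      ok <- abs(dt) <= cfg$tolerance_ns
      out$pupil_diameter[ok] <- ed[ei[ok]]
      out$pupil_dt_ns[ok] <- dt[ok]
      if (any(!ok)) {
        cg_log(sprintf("align_streams: %d frame(s) without a pupil sample within tolerance",
                       sum(!ok)))
      }
    }
  }
  out
}

#' Write an aligned table as CSV for inspection
#' @param aligned Output of [align_streams()].
#' @param path Destination file.
#' @export
write_aligned <- function(aligned, path) {
  write_csv_formatted(aligned, path, list(
    frame_index = "%d", frame_timestamp = FMT_TS,
    gaze_px_x = FMT_REAL, gaze_px_y = FMT_REAL,
    gaze_norm_x = FMT_REAL, gaze_norm_y = FMT_REAL,
    confidence = "%.6f", on_frame = "s", pupil_diameter = FMT_REAL,
    gaze_dt_ns = "%.0f", pupil_dt_ns = "%.0f"))
}
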