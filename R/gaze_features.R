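#' Test a gaze sample against detected boxes (dynamic area of interest)
#'
#' Each detected player's bounding box acts as a per-frame area of interest.
#' An on-frame gaze point that lies inside at least one box is assigned to
#' the smallest-area containing box (ties broken by higher detector
#' confidence, then lower track id / first listed). Off-frame or unmatched
#' gaze never hits.
#'
#' @param record One row of the aligned table ([align_streams()]).
#' @param boxes Clipped bounding-box data frame for the same frame.
#' @return List: `frame_index`, `hit` (logical), `box` (one-row data frame
#'   or `NULL`).
#' @export
assign_gaze_to_box <- function(record, boxes) {
  res <- list(frame_index = record$frame_index, hit = FALSE, box = NULL)
  if (!isTRUE(record$on_frame) || nrow(boxes) == 0L) return(res)
  x <- record$gaze_px_x; y <- record$gaze_px_y
  inside <- x >= boxes$x_min & x < boxes$x_max &
            y >= boxes$y_min & y < boxes$y_max
  if (!any(inside)) return(res)
  cand <- boxes[inside, , drop = FALSE]
  area <- (cand$x_max - cand$x_min) * (cand$y_max - cand$y_min)
  tid <- ifelse(is.na(cand$track_id), .Machine$integer.max, cand$track_id)
  ord <- order(area, -cand$confidence, tid)
  res$hit <- TRUE
  res$box <- cand[ord[[1L]], , drop = FALSE]
  res
}

#' Run the full per-frame classification pipeline
#'
#' For every aligned scene frame: detect persons, test the gaze point
#' against the boxes (dynamic AOI), crop the hit box, segment the upper
#' clothing, multiply by the binary mask, extract the dominant color, and
#' classify the team. Any per-frame stage failure downgrades that frame to
#' `team = "unknown"` (if the AOI hit stood) or `"none"` and the run
#' continues; a frame is never fatal.
#'
#' @param session A `neon_session`.
#' @param aligned Aligned table from [align_streams()].
#' @param detector Detector backend ([mock_detector()] or an adapter).
#' @param segmenter Segmenter backend ([mock_segmenter()] or an adapter).
#' @param palette A [team_palette()].
#' @return Data frame with one row per frame: `frame_index`,
#'   `frame_timestamp`, `hit`, `team` (`A`/`B`/`unknown`/`none`), hit box
#'   extents, dominant color, `n_pixels`, `pupil_diameter`.
#' @export
classify_frames <- function(session, aligned, detector, segmenter, palette) {
  n <- nrow(aligned)
  out <- data.frame(
    frame_index = aligned$frame_index,
    frame_timestamp = aligned$frame_timestamp,
    hit = FALSE, team = "none",
    box_x_min = NA_real_, box_y_min = NA_real_,
    box_x_max = NA_real_, box_y_max = NA_real_,
    dominant_r = NA_real_, dominant_g = NA_real_, dominant_b = NA_real_,
    n_pixels = NA_integer_,
    pupil_diameter = aligned$pupil_diameter)
  for (i in seq_len(n)) {
    rec <- aligned[i, ]
    team <- "none"
    tryCatch({
      frame <- get_frame(session, rec$frame_index)
      boxes <- detect_persons(frame, detector)
      hit <- assign_gaze_to_box(rec, boxes)
      if (hit$hit) {
        out$hit[i] <- TRUE
        team <- "unknown"
        b <- hit$box
        out$box_x_min[i] <- b$x_min; out$box_y_min[i] <- b$y_min
        out$box_x_max[i] <- b$x_max; out$box_y_max[i] <- b$y_max
        patch <- crop_frame(frame, b)
        mask <- segment_clothing(patch, segmenter)
        if (sum(mask) > 0L) {
          masked <- apply_mask(patch, mask)
          obs <- extract_dominant_color(masked, mask, rec$frame_index)
          out$dominant_r[i] <- obs$dominant[[1]]
          out$dominant_g[i] <- obs$dominant[[2]]
          out$dominant_b[i] <- obs$dominant[[3]]
          out$n_pixels[i] <- obs$n_pixels
          team <- classify_team(obs, palette)
        } else {
          cg_log(sprintf("frame %d: empty segmentation; team unknown",
                         rec$frame_index))
        }
      }
    }, error = function(e) {
      cg_warn(sprintf("frame %d: %s; frame downgraded", rec$frame_index,
                      conditionMessage(e)))
      if (out$hit[i]) team <<- "unknown"
    })
    out$team[i] <- team
  }
  out
}

#' Segment per-frame team labels into gaze events
#'
#' A gaze event is a maximal run of consecutive frames assigned to the same
#' team (A or B). Frames labeled `unknown` or `none` break runs; runs
#' shorter than `min_event_frames` are discarded (the default 2 frames,
#' about 67 ms at 30 Hz, suppresses single-frame flicker from detection
#' noise).
#'
#' @param assignments Frame-ordered assignment table ([classify_frames()]).
#' @param min_event_frames Minimum run length kept.
#' @return Data frame: `team`, `start_frame`, `end_frame` (inclusive),
#'   `duration_frames`.
#' @export
segment_gaze_events <- function(assignments, min_event_frames = 2L) {
  empty <- data.frame(team = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration_frames = integer(0))
  if (nrow(assignments) == 0L) return(empty)
  r <- rle(assignments$team)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("A", "B") & r$lengths >= min_event_frames
  if (!any(keep)) return(empty)
  data.frame(team = r$values[keep],
             start_frame = assignments$frame_index[starts[keep]],
             end_frame = assignments$frame_index[ends[keep]],
             duration_frames = r$lengths[keep])
}

#' Read / write a phase-annotation table
#'
#' Expert annotators label spans of the recording with the game phase. The
#' CSV columns are `start_ts`, `end_ts` (nanoseconds, half-open span),
#' `phase` (`attack`/`defense`, from the wearer's perspective) and
#' `attacking_team` (`A`/`B`).
#'
#' @param path CSV file path.
#' @return Data frame of phase segments, validated (non-overlapping,
#'   `start_ts < end_ts`).
#' @export
read_phases <- function(path) {
  if (!file.exists(path)) cg_stop("phase annotation file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phases(df)
}

#' @rdname read_phases
#' @param phases Phase data frame.
#' @export
write_phases <- function(phases, path) {
  write_csv_formatted(
    phases[, c("start_ts", "end_ts", "phase", "attacking_team")], path,
    list(start_ts = FMT_TS, end_ts = FMT_TS, phase = "s", attacking_team = "s"))
}

validate_phases <- function(df) {
  need <- c("start_ts", "end_ts", "phase", "attacking_team")
  if (!all(need %in% names(df))) {
    cg_stop("phase table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(df$start_ts >= df$end_ts)) cg_stop("phase segment with start_ts >= end_ts")
  df <- df[order(df$start_ts), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start_ts[-1L] < df$end_ts[-nrow(df)])) {
    cg_stop("phase segments overlap")
  }
  if (!all(df$phase %in% c("attack", "defense"))) {
    cg_stop("phase must be 'attack' or 'defense'")
  }
  df
}

# phase label per frame timestamp; NA outside all segments
phase_of_timestamps <- function(ts, phases) {
  phases <- validate_phases(phases)
  idx <- findInterval(ts, phases$start_ts)
  lab <- rep(NA_character_, length(ts))
  ok <- idx >= 1L
  ok[ok] <- ts[ok] < phases$end_ts[idx[ok]]
  lab[ok] <- phases$phase[idx[ok]]
  lab
}

#' Build the per-observer feature table
#'
#' Aggregates the frame assignments into the standard analysis cells: for
#' each observed team (A, B) and game phase (attack, defense), the number
#' of gaze events whose start frame falls in the phase, the number of
#' frames so labeled, and the mean and standard deviation of the pupil
#' diameter over those frames (missing diameters excluded). `total` rows
#' per phase sum the counts over teams and pool the diameters.
#'
#' @param assignments Assignment table ([classify_frames()]).
#' @param events Gaze events ([segment_gaze_events()]).
#' @param phases Phase segments ([read_phases()]).
#' @param observer_role Label stored in the table (e.g. `lead_referee`).
#' @return Data frame of class `feature_table`: `observer_role`, `team`,
#'   `phase`, `gaze_event_count`, `gaze_frame_count`, `pupil_mean`,
#'   `pupil_sd`, `n_pupil`.
#' @export
build_feature_table <- function(assignments, events, phases,
                                observer_role = "observer") {
  phases <- validate_phases(phases)
  frame_phase <- phase_of_timestamps(assignments$frame_timestamp, phases)
  ev_phase <- if (nrow(events) > 0L) {
    start_ts <- assignments$frame_timestamp[
      match(events$start_frame, assignments$frame_index)]
    phase_of_timestamps(start_ts, phases)
  } else character(0)

  cells <- expand.grid(team = c("A", "B"), phase = c("attack", "defense"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tm <- cells$team[i]; ph <- cells$phase[i]
    in_cell <- assignments$team == tm & !is.na(frame_phase) & frame_phase == ph
    dia <- assignments$pupil_diameter[in_cell]
    dia <- dia[!is.na(dia)]
    data.frame(observer_role = observer_role, team = tm, phase = ph,
               gaze_event_count = sum(events$team == tm & !is.na(ev_phase) &
                                        ev_phase == ph),
               gaze_frame_count = sum(in_cell),
               pupil_mean = if (length(dia)) mean(dia) else NA_real_,
               pupil_sd = if (length(dia) > 1L) stats::sd(dia) else
                 if (length(dia) == 1L) 0 else NA_real_,
               n_pupil = length(dia))
  })
  per_team <- do.call(rbind, rows)

  totals <- lapply(c("attack", "defense"), function(ph) {
    sel <- per_team$phase == ph
    in_tot <- assignments$team %in% c("A", "B") & !is.na(frame_phase) &
      frame_phase == ph
    dia <- assignments$pupil_diameter[in_tot]
    dia <- dia[!is.na(dia)]
    data.frame(observer_role = observer_role, team = "total", phase = ph,
               gaze_event_count = sum(per_team$gaze_event_count[sel]),
               gaze_frame_count = sum(per_team$gaze_frame_count[sel]),
               pupil_mean = if (length(dia)) mean(dia) else NA_real_,
               pupil_sd = if (length(dia) > 1L) stats::sd(dia) else
                 if (length(dia) == 1L) 0 else NA_real_,
               n_pupil = length(dia))
  })
  out <- rbind(per_team, do.call(rbind, totals))
  class(out) <- c("feature_table", class(out))
  out
}

#' Write / read a feature table CSV
#' @param features A `feature_table`.
#' @param path Destination CSV.
#' @export
write_feature_table <- function(features, path) {
  write_csv_formatted(as.data.frame(features), path, list(
    observer_role = "s", team = "s", phase = "s",
    gaze_event_count = "%d", gaze_frame_count = "%d",
    pupil_mean = FMT_REAL, pupil_sd = FMT_REAL, n_pupil = "%d"))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", class(out))
  out
}
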