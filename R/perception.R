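#' Construct a table of bounding boxes
#'
#' Boxes use half-open integer pixel intervals: a box covers columns
#' `x_min .. x_max - 1` and rows `y_min .. y_max - 1` of the frame, with the
#' origin at the top-left corner.
#'
#' @param x_min,y_min,x_max,y_max Box extents in pixels (vectorized).
#' @param class_label Detector class per box (only `"person"` is analyzed).
#' @param confidence Detector confidence in `[0, 1]`.
#' @param track_id Optional integer track identity.
#' @return Data frame with one row per box.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max,
                         class_label = "person", confidence = 1,
                         track_id = NA_integer_) {
  df <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                   x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                   class_label = class_label, confidence = confidence,
                   track_id = as.integer(track_id))
  bad <- df$x_min >= df$x_max | df$y_min >= df$y_max
  if (any(bad)) cg_stop("bounding_box: degenerate box (min >= max) at row %d",
                        which(bad)[[1L]])
  df
}

empty_boxes <- function() {
  bounding_box(0, 0, 1, 1)[0, ]
}

#' Clip boxes to frame bounds
#' @param boxes Bounding-box data frame.
#' @param width,height Frame dimensions in pixels.
#' @return The boxes intersected with `[0,width) x [0,height)`; boxes with
#'   no overlap are dropped.
#' @export
clip_boxes <- function(boxes, width, height) {
  if (nrow(boxes) == 0L) return(boxes)
  boxes$x_min <- pmax(boxes$x_min, 0)
  boxes$y_min <- pmax(boxes$y_min, 0)
  boxes$x_max <- pmin(boxes$x_max, width)
  boxes$y_max <- pmin(boxes$y_max, height)
  boxes[boxes$x_min < boxes$x_max & boxes$y_min < boxes$y_max, , drop = FALSE]
}

#' Mock person detector backed by a ground-truth sidecar
#'
#' Returns a detector backend that, instead of running a neural network,
#' reads the true player boxes from a synthetic recording's sidecar (see
#' [generate_session()]). Deterministic by construction, which makes exact
#' end-to-end pipeline tests possible.
#'
#' @param ground_truth Ground-truth object (or path to `sidecar.json`).
#' @return A detector backend (list with `name`, `deterministic`, `detect`).
#' @export
mock_detector <- function(ground_truth) {
  gt <- load_ground_truth(ground_truth)
  list(
    name = "mock-sidecar-detector",
    deterministic = TRUE,
    detect = function(frame, frame_index) {
      fr <- gt$frames[[frame_index + 1L]]
      if (is.null(fr) || length(fr$boxes) == 0L) return(empty_boxes())
      do.call(rbind, lapply(seq_along(fr$boxes), function(i) {
        b <- fr$boxes[[i]]
        bounding_box(b$x_min, b$y_min, b$x_max, b$y_max,
                     confidence = b$confidence %||% 1, track_id = i)
      }))
    })
}

#' Mock clothing segmenter backed by a ground-truth sidecar
#'
#' Returns the painted jersey region of the player whose box the patch was
#' cropped from, expressed in patch coordinates, as a binary mask.
#'
#' @inheritParams mock_detector
#' @return A segmenter backend (list with `name`, `deterministic`, `segment`).
#' @export
mock_segmenter <- function(ground_truth) {
  gt <- load_ground_truth(ground_truth)
  list(
    name = "mock-sidecar-segmenter",
    deterministic = TRUE,
    segment = function(patch, frame_index, box) {
      h <- dim(patch)[1]; w <- dim(patch)[2]
      mask <- matrix(0L, h, w)
      fr <- gt$frames[[frame_index + 1L]]
      if (is.null(fr)) return(mask)
      for (j in fr$jerseys) {
        # intersect jersey rectangle with the crop, shift to patch coords
        x0 <- max(j$x_min, box$x_min); x1 <- min(j$x_max, box$x_max)
        y0 <- max(j$y_min, box$y_min); y1 <- min(j$y_max, box$y_max)
        if (x0 < x1 && y0 < y1) {
          rows <- (y0 - box$y_min + 1):(y1 - box$y_min)
          cols <- (x0 - box$x_min + 1):(x1 - box$x_min)
          mask[rows, cols] <- 1L
        }
      }
      mask
    })
}

load_ground_truth <- function(ground_truth) {
  if (is.character(ground_truth)) {
    p <- if (dir.exists(ground_truth)) file.path(ground_truth, "sidecar.json")
         else ground_truth
    ground_truth <- jsonlite::read_json(p, simplifyVector = FALSE)
  }
  ground_truth
}

#' Detect persons in a scene frame
#'
#' Runs the detector backend, keeps only `"person"` detections, clips boxes
#' to the frame, and sorts them by descending confidence. A backend failure
#' on a frame yields an empty detection list with a warning; the run
#' continues (robustness over completeness on single frames).
#'
#' @param frame Image array (height x width x 3) with attribute
#'   `frame_index` (as returned by [get_frame()]).
#' @param backend A detector backend, e.g. [mock_detector()].
#' @return Bounding-box data frame sorted by descending confidence.
#' @export
detect_persons <- function(frame, backend) {
  if (is.null(frame) || length(frame) == 0L) cg_stop("detect_persons: empty frame")
  fi <- attr(frame, "frame_index") %||% NA_integer_
  boxes <- tryCatch(backend$detect(frame, fi), error = function(e) {
    cg_warn(sprintf("detector '%s' failed on frame %s: %s; frame skipped",
                    backend$name, fi, conditionMessage(e)))
    empty_boxes()
  })
  if (nrow(boxes) == 0L) return(boxes)
  boxes <- boxes[boxes$class_label == "person", , drop = FALSE]
  boxes <- clip_boxes(boxes, dim(frame)[2], dim(frame)[1])
  boxes[order(-boxes$confidence), , drop = FALSE]
}

#' Crop a frame to a bounding box
#'
#' @param frame Image array (height x width x 3).
#' @param box One-row bounding-box data frame (integer, clipped).
#' @return Copied patch of dimensions `(y_max - y_min) x (x_max - x_min) x 3`
#'   with attributes `frame_index` and `box` for downstream backends.
#' @export
crop_frame <- function(frame, box) {
  if (nrow(box) != 1L) cg_stop("crop_frame: exactly one box expected")
  x0 <- box$x_min; x1 <- box$x_max; y0 <- box$y_min; y1 <- box$y_max
  if (x1 <= x0 || y1 <= y0) cg_stop("crop_frame: degenerate box")
  if (x0 < 0 || y0 < 0 || x1 > dim(frame)[2] || y1 > dim(frame)[1]) {
    cg_stop("crop_frame: box exceeds frame bounds; clip first")
  }
  patch <- frame[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  attr(patch, "frame_index") <- attr(frame, "frame_index")
  attr(patch, "box") <- box
  patch
}

#' Segment upper clothing within a patch
#'
#' Applies the segmentation backend to a cropped player patch and reduces
#' the result to a binary mask (1 = upper-clothing pixel) of identical
#' geometry. A backend failure yields an all-zero mask with a warning.
#'
#' @param patch Patch from [crop_frame()].
#' @param backend A segmenter backend, e.g. [mock_segmenter()].
#' @return Integer matrix of 0/1 with the patch's height and width.
#' @export
segment_clothing <- function(patch, backend) {
  if (is.null(patch) || length(patch) == 0L) cg_stop("segment_clothing: empty patch")
  fi <- attr(patch, "frame_index") %||% NA_integer_
  box <- attr(patch, "box")
  mask <- tryCatch(backend$segment(patch, fi, box), error = function(e) {
    cg_warn(sprintf("segmenter '%s' failed on frame %s: %s; empty mask",
                    backend$name, fi, conditionMessage(e)))
    matrix(0L, dim(patch)[1], dim(patch)[2])
  })
  if (!all(dim(mask) == dim(patch)[1:2])) {
    cg_stop("segment_clothing: mask geometry %dx%d does not match patch %dx%d",
            dim(mask)[1], dim(mask)[2], dim(patch)[1], dim(patch)[2])
  }
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L))) cg_stop("segment_clothing: mask not binary")
  mask
}

#' Element-wise mask multiplication
#'
#' Keeps patch pixels under the mask support and zeroes everything else:
#' `out = patch * mask`, applied to every channel.
#'
#' @param patch Image array (h x w x 3).
#' @param mask Binary matrix (h x w).
#' @return Masked image of the same dimensions.
#' @export
apply_mask <- function(patch, mask) {
  if (!all(dim(mask) == dim(patch)[1:2])) {
    cg_stop("apply_mask: dimension mismatch (mask %dx%d vs patch %dx%d)",
            dim(mask)[1], dim(mask)[2], dim(patch)[1], dim(patch)[2])
  }
  patch * array(as.numeric(mask), dim = dim(patch))
}

#' Annotate a frame with detection boxes and the gaze point
#'
#' Draws box outlines (red by default) and a filled gaze dot (cyan), the
#' standard overlay for visual inspection of detection-plus-gaze output.
#'
#' @param frame Image array (h x w x 3).
#' @param boxes Bounding-box data frame.
#' @param gaze_px Length-2 numeric `(x, y)` in pixels, or `NULL`.
#' @param box_color,dot_color RGB triples in `[0, 1]`.
#' @param thickness Outline thickness in pixels.
#' @param dot_radius Gaze-dot radius in pixels.
#' @return The annotated image array.
#' @export
annotate_frame <- function(frame, boxes, gaze_px = NULL,
                           box_color = c(1, 0, 0), dot_color = c(0, 1, 1),
                           thickness = 2L, dot_radius = 4L) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  img <- frame
  paint <- function(rows, cols, col) {
    rows <- rows[rows >= 1 & rows <= h]; cols <- cols[cols >= 1 & cols <= w]
    if (length(rows) && length(cols)) {
      for (ch in 1:3) img[rows, cols, ch] <<- col[ch]
    }
  }
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    rs <- (b$y_min + 1):b$y_max; cs <- (b$x_min + 1):b$x_max
    tk <- seq_len(thickness) - 1L
    paint(b$y_min + 1L + tk, cs, box_color)
    paint(b$y_max - tk, cs, box_color)
    paint(rs, b$x_min + 1L + tk, box_color)
    paint(rs, b$x_max - tk, box_color)
  }
  if (!is.null(gaze_px) && all(is.finite(gaze_px))) {
    cx <- round(gaze_px[[1]]); cy <- round(gaze_px[[2]])
    for (dy in -dot_radius:dot_radius) for (dx in -dot_radius:dot_radius) {
      if (dx * dx + dy * dy <= dot_radius^2) {
        paint(cy + dy + 1L, cx + dx + 1L, dot_color)
      }
    }
  }
  img
}
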