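#' Device specification for a head-mounted eye tracker
#'
#' Describes the camera geometry and sampling rates of the recording device.
#' Defaults follow the Pupil Labs Neon: a forward-facing scene (point-of-view)
#' camera at 1600 x 1200 pixels and 30 Hz, and infrared eye cameras sampled
#' at 200 Hz.
#'
#' @param scene_width,scene_height Scene-camera resolution in pixels.
#' @param scene_rate Scene-camera frame rate in Hz.
#' @param eye_rate Eye-camera (gaze / pupil) sampling rate in Hz.
#' @return An object of class `device_spec`.
#' @examples
#' device_spec()
#' device_spec(scene_width = 320, scene_height = 240)
#' @export
device_spec <- function(scene_width = 1600, scene_height = 1200,
                        scene_rate = 30, eye_rate = 200) {
  vals <- c(scene_width = scene_width, scene_height = scene_height,
            scene_rate = scene_rate, eye_rate = eye_rate)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    cg_stop("device_spec: all fields must be finite and > 0")
  }
  structure(list(scene_width = as.integer(scene_width),
                 scene_height = as.integer(scene_height),
                 scene_rate = scene_rate,
                 eye_rate = eye_rate),
            class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("<device_spec> scene %dx%d @ %g Hz, eyes @ %g Hz\n",
              x$scene_width, x$scene_height, x$scene_rate, x$eye_rate))
  invisible(x)
}

# nanoseconds per scene frame
frame_period_ns <- function(device) 1e9 / device$scene_rate
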