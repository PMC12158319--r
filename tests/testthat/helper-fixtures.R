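# Shared fixture builders. All fixtures are generated in code at test time.

options(courtgaze.quiet = TRUE)

# a small, fast synthetic recording; returns list(dir, ground_truth)
make_recording <- function(seed = 7, n_frames = 90L, ...) {
  dir <- file.path(tempfile("rec"), "r")
  res <- generate_session(scene_script(seed = seed, n_frames = n_frames, ...),
                          dir)
  res
}

test_device <- function() device_spec(scene_width = 320, scene_height = 240)

# uniform color patch (h x w x 3), values in 0..255
make_patch <- function(h, w, rgb) {
  array(rep(rgb / 255, each = h * w), dim = c(h, w, 3))
}

# independent sRGB (0..255) -> CIELAB oracle, standard D65 formulas
oracle_lab <- function(rgb) {
  u <- rgb / 255
  lin <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
  Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
  Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  c(116 * f(Y) - 16, 500 * (f(X / 0.95047) - f(Y)),
    200 * (f(Y) - f(Z / 1.08883)))
}

# brute-force nearest-sample alignment oracle: for each query timestamp,
# scan all reference samples (ties resolve to the first = earlier sample)
oracle_nearest <- function(query, ref) {
  vapply(query, function(q) which.min(abs(ref - q)), integer(1))
}

# session object built directly in memory (no disk) for alignment tests
make_session_ts <- function(world_ts, gaze_ts, eye_ts = numeric(0),
                            device = test_device()) {
  gaze <- data.frame(timestamp = gaze_ts,
                     gaze_x = seq_along(gaze_ts) %% device$scene_width,
                     gaze_y = seq_along(gaze_ts) %% device$scene_height,
                     confidence = rep(1, length(gaze_ts)))
  eye <- data.frame(timestamp = eye_ts,
                    pupil_left = rep(NA_real_, length(eye_ts)),
                    pupil_right = rep(NA_real_, length(eye_ts)),
                    pupil_diameter = 3 + seq_along(eye_ts) * 1e-3)
  structure(list(device = device,
                 world = data.frame(frame_index = seq_along(world_ts) - 1L,
                                    timestamp = world_ts),
                 gaze = gaze, eye_states = eye,
                 events = data.frame(timestamp = numeric(0),
                                     name = character(0)),
                 fixations = data.frame(), saccades = data.frame(),
                 blinks = data.frame(), imu = data.frame(),
                 frame_files = character(0), source_dir = "<memory>"),
            class = "neon_session")
}
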