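test_that("mock detector reproduces painted player extents exactly", {
  rec <- make_recording(seed = 11, n_frames = 10L, n_players_per_team = 2L)
  s <- read_session(rec$dir, device = test_device())
  det <- mock_detector(rec$dir)              # reads sidecar.json
  frame <- get_frame(s, 4)
  boxes <- detect_persons(frame, det)
  expect_equal(nrow(boxes), 4L)
  gt <- rec$ground_truth$frames[[5]]$boxes
  for (b in gt) {
    hit <- boxes$x_min == b$x_min & boxes$y_min == b$y_min &
      boxes$x_max == b$x_max & boxes$y_max == b$y_max
    expect_equal(sum(hit), 1L)
    # painted pixels: jersey band inside the box differs from background
    expect_false(all(frame[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max, 1] ==
                       frame[1, 1, 1]))
  }
})

test_that("an empty frame yields no detections and a failing backend warns", {
  empty_backend <- list(name = "null", deterministic = TRUE,
                        detect = function(frame, idx) {
                          bounding_box(0, 0, 1, 1)[0, ]
                        })
  frame <- make_patch(60, 80, c(190, 160, 120))
  expect_equal(nrow(detect_persons(frame, empty_backend)), 0L)
  bad <- list(name = "bad", deterministic = TRUE,
              detect = function(frame, idx) stop("backend exploded"))
  expect_warning(boxes <- detect_persons(frame, bad), "backend exploded")
  expect_equal(nrow(boxes), 0L)              # run continues with empty list
})

test_that("boxes are clipped to frame bounds by interval intersection", {
  frame <- make_patch(100, 120, c(10, 10, 10))
  backend <- list(name = "half-out", deterministic = TRUE,
                  detect = function(frame, idx) {
                    bounding_box(c(-20, 100), c(-10, 60), c(30, 160), c(50, 130))
                  })
  boxes <- detect_persons(frame, backend)
  # oracle: interval intersection with [0,120) x [0,100)
  expect_equal(sort(boxes$x_min), pmax(c(-20, 100), 0))
  expect_equal(sort(boxes$x_max), sort(pmin(c(30, 160), 120)))
  expect_equal(sort(boxes$y_max), sort(pmin(c(50, 130), 100)))
  expect_true(all((boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min) > 0))
})

test_that("crop copies the exact half-open box region", {
  frame <- array(runif(40 * 50 * 3), dim = c(40, 50, 3))
  attr(frame, "frame_index") <- 0L
  full <- crop_frame(frame, bounding_box(0, 0, 50, 40))
  expect_equal(dim(full), dim(frame))
  expect_equal(full[, , ], frame[, , ])
  b <- bounding_box(5, 8, 15, 28)            # 10 x 20 box
  patch <- crop_frame(frame, b)
  expect_equal(dim(patch), c(20, 10, 3))
  expect_equal(patch[1, 1, ], frame[9, 6, ]) # patch[0,0] == frame[y_min, x_min]
  expect_error(crop_frame(frame, data.frame(x_min = 5, y_min = 5, x_max = 5,
                                            y_max = 9, class_label = "person",
                                            confidence = 1, track_id = NA)),
               "degenerate")
})

test_that("mock segmenter returns the painted jersey region exactly", {
  rec <- make_recording(seed = 11, n_frames = 6L)
  s <- read_session(rec$dir, device = test_device())
  det <- mock_detector(rec$dir)
  seg <- mock_segmenter(rec$dir)
  frame <- get_frame(s, 2)
  boxes <- detect_persons(frame, det)
  patch <- crop_frame(frame, boxes[1, ])
  mask <- segment_clothing(patch, seg)
  expect_equal(dim(mask), dim(patch)[1:2])
  # the mask support is exactly the uniformly colored jersey band: all
  # support pixels share one color and no off-support pixel has it
  sup <- which(mask == 1L)
  cols <- cbind(patch[, , 1][sup], patch[, , 2][sup], patch[, , 3][sup])
  expect_true(nrow(unique(cols)) == 1L)
  jcol <- cols[1, ]
  off <- which(mask == 0L)
  off_cols <- cbind(patch[, , 1][off], patch[, , 2][off], patch[, , 3][off])
  expect_false(any(apply(off_cols, 1, function(p) all(p == jcol))))
})

test_that("segmentation failure yields an all-zero mask; geometry always matches", {
  bad <- list(name = "bad", deterministic = TRUE,
              segment = function(patch, idx, box) stop("no weights"))
  patch <- make_patch(12, 7, c(50, 60, 70))
  expect_warning(mask <- segment_clothing(patch, bad), "no weights")
  expect_equal(sum(mask), 0L)
  expect_equal(dim(mask), c(12, 7))
  # dimension property over random patch sizes
  set.seed(11)
  trivial <- list(name = "t", deterministic = TRUE,
                  segment = function(patch, idx, box) {
                    matrix(1L, dim(patch)[1], dim(patch)[2])
                  })
  for (k in 1:100) {
    h <- sample(1:40, 1); w <- sample(1:40, 1)
    m <- segment_clothing(array(runif(h * w * 3), dim = c(h, w, 3)), trivial)
    expect_identical(dim(m), c(h, w))
  }
})

test_that("apply_mask equals the per-pixel multiply oracle", {
  set.seed(5)
  for (k in 1:100) {
    h <- sample(1:20, 1); w <- sample(1:20, 1)
    patch <- array(runif(h * w * 3), dim = c(h, w, 3))
    mask <- matrix(sample(0:1, h * w, replace = TRUE), h, w)
    out <- apply_mask(patch, mask)
    oracle <- patch
    for (ch in 1:3) for (i in 1:h) for (j in 1:w) {
      oracle[i, j, ch] <- patch[i, j, ch] * mask[i, j]
    }
    expect_equal(out, oracle)
  }
})

test_that("mask arithmetic: identity, annihilator, idempotence, support", {
  patch <- array(runif(15 * 10 * 3), dim = c(15, 10, 3))
  ones <- matrix(1L, 15, 10); zeros <- matrix(0L, 15, 10)
  expect_equal(apply_mask(patch, ones), patch)
  expect_true(all(apply_mask(patch, zeros) == 0))
  mask <- matrix(sample(0:1, 150, replace = TRUE), 15, 10)
  once <- apply_mask(patch, mask)
  expect_equal(apply_mask(once, mask), once)       # idempotent in the mask
  nz <- apply(once, c(1, 2), function(p) any(p != 0))
  expect_true(all(which(nz) %in% which(mask == 1)))  # support containment
  expect_error(apply_mask(patch, matrix(1L, 3, 3)), "dimension mismatch")
})
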