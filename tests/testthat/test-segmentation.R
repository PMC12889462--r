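test_that("temporal median background recovers the clean plate", {
  # constant stack
  fr <- replicate(4, matrix(3, 10, 10), simplify = FALSE)
  expect_equal(estimate_background(fr), matrix(3, 10, 10))
  # drifting bright square over flat background value b = 2
  b <- 2
  fr2 <- lapply(1:9, function(i) {
    m <- matrix(b, 20, 20)
    m[i + 1:3, i + 1:3] <- 9
    m
  })
  bg <- estimate_background(fr2, stride = 1)
  expect_equal(bg, matrix(b, 20, 20))
  expect_warning(one <- estimate_background(fr2[1]), "single frame")
  expect_equal(one, fr2[[1]])
  expect_error(estimate_background(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "constant dimensions")
})

test_that("adaptive threshold is strictly binary and recovers a square", {
  img <- matrix(0, 40, 40)
  expect_true(all(adaptive_threshold(img, 0, window = 9, offset = 0.1) == 0))
  img[15:24, 15:24] <- 1
  # window larger than the object so its interior stays above the local mean
  bin <- adaptive_threshold(img, 0, window = 21, offset = 0.2)
  expect_true(all(bin %in% c(0, 1)))
  # square recovered exactly up to a boundary ring of width <= window/2
  expect_true(all(bin[15:24, 15:24] == 1))
  out <- bin
  out[5:34, 5:34] <- 0
  expect_true(all(out == 0))
  expect_error(adaptive_threshold(img, window = 8), "odd")
  expect_error(adaptive_threshold(img, window = 99), "larger than")
})

test_that("signed difference suppresses vacated-spot ghosts", {
  bg <- matrix(0, 30, 30)
  bg[10:15, 10:15] <- 1         # object baked into the background
  img <- matrix(0, 30, 30)      # object has left
  pos <- adaptive_threshold(img, bg, window = 9, offset = 0.2,
                            difference = "positive")
  expect_true(all(pos == 0))
  abso <- adaptive_threshold(img, bg, window = 9, offset = 0.2)
  expect_gt(sum(abso), 0)       # absolute difference sees a ghost
})

test_that("blob detection uses 8-connectivity and the area filter", {
  empty <- matrix(0L, 10, 10)
  expect_equal(nrow(detect_blobs(empty)), 0)
  diagonal <- matrix(0L, 5, 5)
  diagonal[2, 2] <- 1L
  diagonal[3, 3] <- 1L
  b <- detect_blobs(diagonal, frame_index = 7)
  expect_equal(nrow(b), 1)           # touching diagonally = one blob
  expect_equal(b$frame, 7L)
  expect_equal(b$area, 2)
  # min_area discards small components
  two <- matrix(0L, 12, 12)
  two[2:3, 2:3] <- 1L                # area 4
  two[8:11, 8:11] <- 1L              # area 16
  expect_equal(nrow(detect_blobs(two, min_area = 5)), 1)
})

test_that("blob areas sum to the foreground pixel count at min_area 1", {
  set.seed(1)
  bin <- matrix(as.integer(runif(900) < 0.2), 30, 30)
  b <- detect_blobs(bin, min_area = 1)
  expect_equal(sum(b$area), sum(bin))
})

test_that("segmentation of rendered frames recovers ground-truth counts", {
  cfg <- tiny_sim(n = 8, seconds = 12, seed = 9)
  truth <- simulate_worms(cfg)
  blobs <- segment_recording(truth, cfg)
  ts <- truth_frame_sizes(truth)
  counts <- table(blobs$frame)
  match_rate <- mean(as.integer(counts[as.character(ts$frame)]) ==
                       lengths(ts$sizes))
  expect_gte(match_rate, 0.98)
})

test_that("segment_frames applies the stride", {
  cfg <- tiny_sim(n = 3, seconds = 3, seed = 2)
  truth <- simulate_worms(cfg)
  frames <- render_frames(truth, cfg)
  tab <- segment_frames(frames, stride = 3, window = 15, offset = 0.2)
  expect_equal(max(tab$frame), ceiling(length(frames) / 3))
})
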