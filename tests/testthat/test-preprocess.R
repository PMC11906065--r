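make_rgb_ramp <- function(active_channel = 1L, h = 10L, w = 10L, t_n = 8L) {
  frames <- array(20, c(h, w, 3L, t_n))
  for (t in seq_len(t_n)) {
    frames[, , active_channel, t] <- 10 * t  # ramp only in one channel
  }
  video_stack(frames, frame_rate = 10)
}

test_that("channel auto-selection picks the dynamic channel", {
  for (ch in 1:3) {
    v <- make_rgb_ramp(active_channel = ch)
    out <- isolate_fluorescence_channel(v, strategy = "auto")
    expect_equal(attr(out, "channel"), ch)
    expect_equal(dim(out$frames)[3], 1L)
    expect_equal(out$frames[1, 1, 1, 3], if (ch == 0) 20 else 30)
  }
})

test_that("fixed channel override and single-channel identity hold", {
  v <- make_rgb_ramp(active_channel = 1L)
  out <- isolate_fluorescence_channel(v, strategy = "fixed", channel = 3L)
  expect_equal(attr(out, "channel"), 3L)
  expect_true(all(out$frames == 20))

  mono <- ramp_video()
  expect_identical(isolate_fluorescence_channel(mono)$frames, mono$frames)
})

test_that("foreground thresholding is monotone and errors when empty", {
  v <- ramp_video(t_n = 6L)  # pixel maxima in 1..12 roughly
  m_all <- threshold_foreground(v, threshold = -1)
  expect_true(all(m_all == 1L))

  expect_error(threshold_foreground(v, threshold = max(v$frames)),
               "no foreground")

  # raising the threshold never adds pixels
  thresholds <- seq(0, max(v$frames) - 1, length.out = 8)
  masks <- lapply(thresholds, function(th) threshold_foreground(v, threshold = th))
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  }
})

test_that("fractional threshold recovers the phantom chamber union", {
  ph <- generate_phantom(small_phantom_config(seed = 5))
  chan <- isolate_fluorescence_channel(ph$video)
  fg <- threshold_foreground(chan, fraction = 0.2, statistic = "max")
  truth_union <- (ph$truth$chamber_masks[[1]] | ph$truth$chamber_masks[[2]]) * 1L
  expect_gte(jaccard(fg, truth_union), 0.95)
})

test_that("time-series extraction enumerates row-major and is lossless", {
  v <- ramp_video(h = 8L, w = 8L, t_n = 5L)
  checker <- matrix(as.integer((row(matrix(0, 4, 4)) +
                                  col(matrix(0, 4, 4))) %% 2 == 0), 4, 4)
  checker_full <- matrix(0L, 8, 8)
  checker_full[1:4, 1:4] <- checker
  px <- extract_timeseries(v, checker_full)
  expect_equal(nrow(px$traces), sum(checker_full))
  # hand-enumerated row-major coordinates of the 4x4 checkerboard corner
  expect_equal(px$coords[1:4, "row"], c(1, 1, 2, 2), ignore_attr = TRUE)
  expect_equal(px$coords[1:4, "col"], c(1, 3, 2, 4), ignore_attr = TRUE)
  # traces match the source pixels
  for (i in c(1L, nrow(px$coords))) {
    expect_equal(px$traces[i, ],
                 v$frames[px$coords[i, 1], px$coords[i, 2], 1, ])
  }

  # all-ones mask reshapes back to the exact video
  all_on <- matrix(1L, 8, 8)
  px_all <- extract_timeseries(v, all_on)
  expect_equal(nrow(px_all$traces), 64L)
  rebuilt <- array(0, dim(v$frames))
  for (i in seq_len(64)) {
    rebuilt[px_all$coords[i, 1], px_all$coords[i, 2], 1, ] <- px_all$traces[i, ]
  }
  expect_equal(rebuilt, v$frames)

  expect_error(extract_timeseries(v, matrix(0L, 8, 8)), "empty mask")

  # purity: inputs untouched
  before <- v$frames
  invisible(extract_timeseries(v, all_on))
  expect_identical(v$frames, before)
})

test_that("single-pixel mask yields that pixel's trace", {
  v <- ramp_video()
  m <- matrix(0L, 8, 8); m[5, 2] <- 1L
  px <- extract_timeseries(v, m)
  expect_equal(nrow(px$traces), 1L)
  expect_equal(px$traces[1, ], v$frames[5, 2, 1, ])
})
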