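test_that("kinetic curve: onset continuity, pre-arrival zero, peak location", {
  kin <- chamber_kinetics(t_arrival = 1, k_in = 2, k_out = 0.1, amplitude = 1)
  times <- seq(0, 30, by = 0.001)
  curve <- kinetic_curve(kin, times)
  expect_true(all(curve[times < 1] == 0))
  expect_equal(kinetic_curve(kin, 1), 0)  # continuous at onset
  expect_true(all(curve >= 0))

  # closed-form peak matches a dense grid argmax
  t_peak <- kinetic_peak_time(kin)
  expect_equal(t_peak, 1 + log((2 + 0.1) / 0.1) / 2)
  expect_equal(times[which.max(curve)], t_peak, tolerance = 2e-3 / t_peak)
  # single interior maximum: rises before, falls after
  d <- diff(curve[times >= 1.001])
  flip <- which(d < 0)[1]
  expect_true(all(d[seq_len(flip - 1)] > -1e-12))
  expect_true(all(d[flip:length(d)] <= 1e-12))

  expect_error(chamber_kinetics(1, 0.5, 0.6, 1), "k_out")
  expect_error(kinetic_curve(kin, c(3, 2, 1)), "non-decreasing")
})

test_that("faster wash-in chamber peaks earlier in the default scene", {
  cfg <- default_phantom_config()
  peaks <- vapply(cfg$chambers,
                  function(ch) kinetic_peak_time(ch$kinetics), numeric(1))
  k_ins <- vapply(cfg$chambers,
                  function(ch) ch$kinetics$k_in, numeric(1))
  expect_equal(order(peaks), order(-k_ins))
})

test_that("noise-free rendering reproduces the clean curves exactly", {
  cfg <- small_phantom_config(seed = 1, noise_sd = 0)
  ph <- generate_phantom(cfg, quantize = FALSE)
  red <- ph$video$frames[, , 1, ]
  for (i in 1:2) {
    mask <- ph$truth$chamber_masks[[i]]
    lin <- which(mask == 1L)
    roi_trace <- vapply(seq_len(dim(red)[3]),
                        function(t) mean(red[, , t][lin]), numeric(1))
    expect_equal(roi_trace, ph$truth$clean_curves[i, ], tolerance = 1e-12)
  }
  # background pixels stay at the background level
  bg <- which(ph$truth$chamber_masks[[1]] == 0L &
                ph$truth$chamber_masks[[2]] == 0L)
  expect_true(all(red[, , 5][bg] == cfg$background_level))
})

test_that("equal kinetics in both chambers give perfectly correlated pixels", {
  kin <- chamber_kinetics(2, 1, 0.1, 0.5)
  cfg <- phantom_config(
    list(
      phantom_chamber(list(type = "rect", row0 = 5, col0 = 5,
                           row1 = 20, col1 = 40), kin),
      phantom_chamber(list(type = "rect", row0 = 40, col0 = 5,
                           row1 = 55, col1 = 40), kin)
    ),
    frame_shape = c(60L, 50L), frame_rate = 10, duration = 12,
    noise = list(gaussian_sd = 0), seed = 1
  )
  ph <- generate_phantom(cfg, quantize = FALSE)
  p1 <- ph$video$frames[10, 10, 1, ]
  p2 <- ph$video$frames[45, 10, 1, ]
  expect_equal(ncc(p1, p2), 1)
})

test_that("seeded noise has the half-normal mean absolute deviation", {
  cfg <- small_phantom_config(seed = 6)  # gaussian sd = 2
  clean <- generate_phantom(small_phantom_config(seed = 6, noise_sd = 0),
                            quantize = FALSE)
  noisy <- generate_phantom(cfg, quantize = FALSE)
  dev <- abs(noisy$video$frames - clean$video$frames)
  # clipping at 0 affects only the far tail at background 10 with sd 2
  expect_gte(length(dev), 1e5)
  expect_gte(mean(dev), 1.4)   # sd * sqrt(2 / pi) = 1.596
  expect_lte(mean(dev), 1.8)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_phantom(small_phantom_config(seed = 3))
  b <- generate_phantom(small_phantom_config(seed = 3))
  expect_identical(a$video$frames, b$video$frames)
  # different seed: same truth, different noise
  c <- generate_phantom(small_phantom_config(seed = 4))
  expect_identical(a$truth$chamber_masks, c$truth$chamber_masks)
  expect_equal(a$truth$clean_curves, c$truth$clean_curves)
  expect_false(identical(a$video$frames, c$video$frames))
})

test_that("default configuration renders without saturating", {
  ph <- generate_phantom(small_phantom_config(seed = 0))
  expect_lt(ph$truth$clip_fraction, 0.001)
  expect_true(all(ph$truth$clean_curves >= 0))
})

test_that("configuration validation rejects bad geometry", {
  kin <- chamber_kinetics(2, 1, 0.1, 0.5)
  expect_error(phantom_config(list(
    phantom_chamber(list(type = "ellipse", center = c(10, 10),
                         semi_axes = c(20, 20)), kin)
  ), frame_shape = c(60L, 60L)), "outside")
  expect_error(phantom_config(list(
    phantom_chamber(list(type = "rect", row0 = 5, col0 = 5,
                         row1 = 30, col1 = 30), kin),
    phantom_chamber(list(type = "rect", row0 = 25, col0 = 25,
                         row1 = 50, col1 = 50), kin)
  ), frame_shape = c(60L, 60L)), "overlap")
  expect_error(phantom_chamber(list(type = "rect", row0 = 1, col0 = 1,
                                    row1 = 5, col1 = 5),
                               chamber_kinetics(2, 1, 0.1, 0.9),
                               amplitude_span = 0.5),
               "dynamic range")
})
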