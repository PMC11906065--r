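# Shared fixtures: a scaled-down dual-chamber phantom (same kinetics and
# amplitude design as the default configuration, quarter-resolution frames
# at 10 fps) keeps most tests fast while exercising the same code paths.

small_phantom_config <- function(seed = 0L, noise_sd = 2,
                                 frame_rate = 10, duration = 20) {
  fast <- phantom_chamber(
    geometry = list(type = "ellipse", center = c(35, 80),
                    semi_axes = c(14, 50)),
    kinetics = chamber_kinetics(t_arrival = 2, k_in = 1.5, k_out = 0.15,
                                amplitude = 0.70),
    amplitude_span = 0.21
  )
  slow <- phantom_chamber(
    geometry = list(type = "ellipse", center = c(85, 80),
                    semi_axes = c(14, 50)),
    kinetics = chamber_kinetics(t_arrival = 3, k_in = 0.5, k_out = 0.05,
                                amplitude = 0.40),
    amplitude_span = 0.25
  )
  phantom_config(list(fast, slow), frame_shape = c(120L, 160L),
                 frame_rate = frame_rate, duration = duration,
                 noise = list(gaussian_sd = noise_sd, poisson_scale = NULL),
                 seed = seed)
}

# A tiny deterministic single-channel video: each pixel's trace is a
# distinct affine ramp, handy for exact-value tests.
ramp_video <- function(h = 8L, w = 8L, t_n = 6L, frame_rate = 10) {
  frames <- array(0, c(h, w, 1L, t_n))
  for (t in seq_len(t_n)) {
    frames[, , 1, t] <- matrix(seq_len(h * w) %% 7 + t, h, w)
  }
  video_stack(frames, frame_rate = frame_rate)
}
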