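# Synthetic dual-chamber perfusion phantom: a bench flow model in software.
# Two chambers fed by a pump through differently sized orifices produce
# distinct ICG wash-in/wash-out intensity profiles; the generator renders
# them into noisy color video with ground-truth masks and noiseless curves.

#' Wash-in / wash-out kinetics of a perfusion chamber
#'
#' The bolus-response model used throughout the package: after first arrival
#' at `t_arrival`, intensity follows
#' `I(t) = amplitude * (1 - exp(-k_in * tau)) * exp(-k_out * tau)` with
#' `tau = t - t_arrival` (0 before arrival). The rising factor captures the
#' rapid inflow of the bolus; the decaying factor the slow clearance. The
#' curve is continuous at onset, has a single interior maximum and tends to 0
#' as `t` grows.
#'
#' @param t_arrival First-arrival time of the bolus in seconds (>= 0).
#' @param k_in Wash-in rate in 1/s (> 0).
#' @param k_out Wash-out decay rate in 1/s (> 0 and < `k_in`: clearance is
#'   slower than inflow).
#' @param amplitude Peak intensity gain as a fraction of the dynamic range,
#'   in (0, 1\].
#' @return An object of class `chamber_kinetics`.
#' @examples
#' kin <- chamber_kinetics(t_arrival = 2, k_in = 1.5, k_out = 0.15,
#'                         amplitude = 0.7)
#' kinetic_peak_time(kin)
#' @export
chamber_kinetics <- function(t_arrival, k_in, k_out, amplitude) {
  check_number(t_arrival, "t_arrival", function(v) v >= 0, "negative")
  check_positive(k_in, "k_in")
  check_positive(k_out, "k_out")
  if (k_out >= k_in) stop("k_out must be smaller than k_in", call. = FALSE)
  check_number(amplitude, "amplitude", function(v) v > 0 & v <= 1,
               "outside (0, 1]")
  structure(
    list(t_arrival = t_arrival, k_in = k_in, k_out = k_out,
         amplitude = amplitude),
    class = "chamber_kinetics"
  )
}

#' Evaluate a chamber kinetic curve
#'
#' @param kin A [chamber_kinetics()].
#' @param times Non-decreasing vector of times in seconds (>= 0).
#' @return Intensity values (fraction of dynamic range), 0 before arrival.
#' @export
kinetic_curve <- function(kin, times) {
  stopifnot(inherits(kin, "chamber_kinetics"))
  check_number(times, "times", function(v) v >= 0, "negative")
  if (is.unsorted(times)) stop("`times` must be non-decreasing", call. = FALSE)
  tau <- times - kin$t_arrival
  out <- numeric(length(times))
  on <- tau >= 0
  out[on] <- kin$amplitude * (1 - exp(-kin$k_in * tau[on])) *
    exp(-kin$k_out * tau[on])
  out
}

#' Closed-form peak time of a chamber kinetic curve
#'
#' Setting the derivative of the wash-in/wash-out product to zero gives the
#' peak at `t_arrival + log((k_in + k_out) / k_out) / k_in`.
#'
#' @param kin A [chamber_kinetics()].
#' @return Peak time in seconds.
#' @export
kinetic_peak_time <- function(kin) {
  stopifnot(inherits(kin, "chamber_kinetics"))
  kin$t_arrival + log((kin$k_in + kin$k_out) / kin$k_out) / kin$k_in
}

#' Define a phantom chamber
#'
#' A chamber is a geometric region (ellipse or rectangle, 1-based pixel
#' coordinates) carrying a kinetic curve. An optional along-flow amplitude
#' gradient varies the local amplitude linearly across the chamber's columns
#' from `amplitude * (1 - span)` to `amplitude * (1 + span)`, emulating
#' non-uniform illumination and depth along the flow axis.
#'
#' @param geometry A list: `list(type = "ellipse", center = c(row, col),
#'   semi_axes = c(row_semi, col_semi))` or `list(type = "rect",
#'   row0, col0, row1, col1)` (inclusive bounds).
#' @param kinetics A [chamber_kinetics()]; its `amplitude` is the chamber's
#'   mean amplitude.
#' @param amplitude_span Relative half-range of the along-flow amplitude
#'   gradient, in \[0, 1); 0 disables the gradient.
#' @return An object of class `phantom_chamber`.
#' @export
phantom_chamber <- function(geometry, kinetics, amplitude_span = 0) {
  stopifnot(inherits(kinetics, "chamber_kinetics"))
  if (!is.list(geometry) || !geometry$type %in% c("ellipse", "rect")) {
    stop("geometry type must be 'ellipse' or 'rect'", call. = FALSE)
  }
  check_number(amplitude_span, "amplitude_span", function(v) v >= 0 & v < 1,
               "outside [0, 1)")
  if (kinetics$amplitude * (1 + amplitude_span) > 1) {
    stop("amplitude gradient exceeds the dynamic range", call. = FALSE)
  }
  structure(
    list(geometry = geometry, kinetics = kinetics,
         amplitude_span = amplitude_span),
    class = "phantom_chamber"
  )
}

# Rasterize a chamber geometry to a 0/1 mask.
chamber_mask <- function(geometry, dim) {
  h <- dim[1]; w <- dim[2]
  if (geometry$type == "ellipse") {
    cr <- geometry$center[1]; cc <- geometry$center[2]
    a <- geometry$semi_axes[1]; b <- geometry$semi_axes[2]
    if (cr - a < 1 || cr + a > h || cc - b < 1 || cc + b > w) {
      stop("chamber geometry extends outside the frame", call. = FALSE)
    }
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- matrix(as.integer(((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1),
                   h, w)
  } else {
    if (geometry$row0 < 1 || geometry$col0 < 1 ||
        geometry$row1 > h || geometry$col1 > w) {
      stop("chamber geometry extends outside the frame", call. = FALSE)
    }
    mask <- matrix(0L, h, w)
    mask[geometry$row0:geometry$row1, geometry$col0:geometry$col1] <- 1L
  }
  mask
}

#' Assemble a phantom configuration
#'
#' @param chambers List of [phantom_chamber()] objects (>= 1); geometries
#'   must not overlap and must lie within the frame.
#' @param frame_shape Frame dimensions `c(H, W)`; default `c(480, 640)`.
#' @param frame_rate Frames per second; default 30.
#' @param duration Video duration in seconds.
#' @param background_level Constant background intensity (0-255 scale).
#' @param noise List: `gaussian_sd` (additive sensor noise standard
#'   deviation in intensity units; 0 disables) and optional `poisson_scale`
#'   (photon-count scale for shot noise; `NULL` disables).
#' @param channel_gains Length-3 RGB multipliers applied to the fluorescence
#'   signal; the dominant channel mimics NIR leakage into one sensor channel.
#' @param seed Integer seed driving every random draw of the generator.
#' @return An object of class `phantom_config`.
#' @seealso [default_phantom_config()] for the canonical two-chamber scene.
#' @export
phantom_config <- function(chambers,
                           frame_shape = c(480L, 640L),
                           frame_rate = 30,
                           duration = 20,
                           background_level = 10,
                           noise = list(gaussian_sd = 2, poisson_scale = NULL),
                           channel_gains = c(1, 0.15, 0.05),
                           seed = 0L) {
  if (!is.list(chambers) || length(chambers) < 1 ||
      !all(vapply(chambers, inherits, logical(1), "phantom_chamber"))) {
    stop("`chambers` must be a non-empty list of phantom_chamber objects",
         call. = FALSE)
  }
  check_positive(frame_rate, "frame_rate")
  check_positive(duration, "duration")
  check_number(background_level, "background_level", function(v) v >= 0,
               "negative")
  if (length(channel_gains) != 3 || any(channel_gains < 0) ||
      max(channel_gains) <= 0) {
    stop("`channel_gains` must be 3 non-negative values, not all zero",
         call. = FALSE)
  }
  if (max(channel_gains) > 1) {
    stop("`channel_gains` must not exceed 1", call. = FALSE)
  }
  masks <- lapply(chambers, function(ch) chamber_mask(ch$geometry, frame_shape))
  overlap <- Reduce(`+`, masks)
  if (any(overlap > 1)) stop("chamber geometries overlap", call. = FALSE)
  t_arr <- vapply(chambers, function(ch) ch$kinetics$t_arrival, numeric(1))
  if (any(t_arr >= duration)) {
    stop("every t_arrival must precede the video end", call. = FALSE)
  }
  structure(
    list(
      chambers = chambers,
      frame_shape = as.integer(frame_shape),
      frame_rate = frame_rate,
      duration = duration,
      background_level = background_level,
      noise = noise,
      channel_gains = channel_gains,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

#' Canonical dual-chamber phantom configuration
#'
#' The package's reference scene: two elliptical chambers stacked
#' vertically (as a bench flow model viewed face-on), a fast-flow chamber on
#' top and a slow-flow chamber below, standing in for flow restrictors with
#' 0.8 mm and 1.2 mm outlet orifices. 480 x 640 at 30 fps for 20 s, 8-bit,
#' fluorescence injected predominantly into the red channel, additive
#' gaussian sensor noise (sd 2/255). Kinetic constants, amplitudes and
#' along-flow amplitude gradients are package defaults chosen so the two
#' chambers have clearly distinct wash-in/wash-out dynamics but comparable
#' accumulated fluorescence; see the package vignette for the rationale.
#'
#' @param seed Integer seed for the noise realization; the geometry and
#'   clean curves do not depend on it.
#' @return A [phantom_config()].
#' @export
default_phantom_config <- function(seed = 0L) {
  fast <- phantom_chamber(
    geometry = list(type = "ellipse", center = c(140, 320),
                    semi_axes = c(55, 200)),
    kinetics = chamber_kinetics(t_arrival = 2, k_in = 1.5, k_out = 0.15,
                                amplitude = 0.70),
    amplitude_span = 0.21
  )
  slow <- phantom_chamber(
    geometry = list(type = "ellipse", center = c(340, 320),
                    semi_axes = c(55, 200)),
    kinetics = chamber_kinetics(t_arrival = 3, k_in = 0.5, k_out = 0.05,
                                amplitude = 0.40),
    amplitude_span = 0.25
  )
  phantom_config(chambers = list(fast, slow), seed = seed)
}

#' Render a phantom configuration into a noisy color video with ground truth
#'
#' Each chamber pixel carries `background + gain_c * amplitude(px) *
#' shape(t) * 255` in every channel `c`; background pixels carry the
#' background level. Seeded gaussian (and optionally Poisson shot) noise is
#' added per pixel, per frame, per channel; intensities are clipped to the
#' 8-bit range. The returned truth holds the chamber masks and the noiseless
#' mean-amplitude intensity curve of each chamber in the dominant channel.
#'
#' @param config A [phantom_config()].
#' @param quantize Round intensities to integers (the camera's behavior);
#'   set `FALSE` for noiseless rendering fidelity studies.
#' @return A list: `video` (a [video_stack()]) and `truth` (class
#'   `phantom_truth`: `chamber_masks`, `clean_curves` (k x T matrix),
#'   `times`, `clip_fraction`, `config`).
#' @export
generate_phantom <- function(config, quantize = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$frame_shape[1]; w <- config$frame_shape[2]
  t_n <- as.integer(round(config$duration * config$frame_rate))
  times <- (seq_len(t_n) - 1) / config$frame_rate
  maxval <- 255

  masks <- lapply(config$chambers,
                  function(ch) chamber_mask(ch$geometry, config$frame_shape))
  # per-chamber linear pixel indices and local amplitudes
  amp <- lapply(seq_along(config$chambers), function(i) {
    ch <- config$chambers[[i]]
    idx <- which(masks[[i]] == 1L)
    cols <- (idx - 1L) %/% h + 1L
    span <- ch$amplitude_span
    if (span > 0 && max(cols) > min(cols)) {
      u <- (cols - min(cols)) / (max(cols) - min(cols))
      a <- ch$kinetics$amplitude * (1 + span * (2 * u - 1))
    } else {
      a <- rep(ch$kinetics$amplitude, length(idx))
    }
    list(idx = idx, a = a)
  })
  # unit-amplitude curve shapes
  shapes <- lapply(config$chambers, function(ch) {
    kin <- ch$kinetics
    unit <- chamber_kinetics(kin$t_arrival, kin$k_in, kin$k_out, 1)
    kinetic_curve(unit, times)
  })
  dominant <- which.max(config$channel_gains)
  clean_curves <- do.call(rbind, lapply(seq_along(shapes), function(i) {
    config$background_level + config$channel_gains[dominant] * maxval *
      mean(amp[[i]]$a) * shapes[[i]]
  }))

  frames <- array(0L, c(h, w, 3L, t_n))
  gaussian_sd <- config$noise$gaussian_sd %||% 0
  poisson_scale <- config$noise$poisson_scale
  n_clipped <- 0
  hw <- h * w
  plane <- 3 * hw  # one RGB frame, in array memory order (h, w, channel)
  # per-chamber indices/amplitudes expanded to all three channels, so a
  # whole time chunk can be rendered in frame-array memory order and
  # written back with one contiguous assignment
  amp3 <- lapply(amp, function(a) {
    list(idx = c(a$idx, hw + a$idx, 2L * hw + a$idx),
         a = c(config$channel_gains[1] * a$a,
               config$channel_gains[2] * a$a,
               config$channel_gains[3] * a$a))
  })
  chunk <- 25L
  with_seed(config$seed, {
    for (start in seq(1L, t_n, by = chunk)) {
      tt <- start:min(start + chunk - 1L, t_n)
      vals <- matrix(config$background_level, plane, length(tt))
      for (i in seq_along(amp3)) {
        vals[amp3[[i]]$idx, ] <- config$background_level +
          maxval * tcrossprod(amp3[[i]]$a, shapes[[i]][tt])
      }
      if (!is.null(poisson_scale)) {
        vals <- stats::rpois(length(vals), vals * poisson_scale) /
          poisson_scale
      }
      if (gaussian_sd > 0) {
        vals <- vals + stats::rnorm(length(vals), sd = gaussian_sd)
      }
      dest <- ((start - 1) * plane + 1):((start - 1) * plane + length(vals))
      if (quantize) {
        iv <- as.integer(vals + 0.5)  # round half up; clamp below
        lo <- which(iv < 0L)
        hi <- which(iv > maxval)
        n_clipped <- n_clipped + length(lo) + length(hi)
        if (length(lo)) iv[lo] <- 0L
        if (length(hi)) iv[hi] <- as.integer(maxval)
        frames[dest] <- iv
        rm(iv, vals)
        invisible(gc(FALSE))  # chunk temporaries dominate the heap
      } else {
        lo <- which(vals < 0)
        hi <- which(vals > maxval)
        n_clipped <- n_clipped + length(lo) + length(hi)
        if (length(lo)) vals[lo] <- 0
        if (length(hi)) vals[hi] <- maxval
        frames[dest] <- vals
      }
    }
  })

  truth <- structure(
    list(
      chamber_masks = masks,
      clean_curves = clean_curves,
      times = times,
      clip_fraction = n_clipped / (h * w * 3 * t_n),
      config = config
    ),
    class = "phantom_truth"
  )
  list(
    video = video_stack(frames, frame_rate = config$frame_rate,
                        bit_depth = 8L),
    truth = truth
  )
}
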