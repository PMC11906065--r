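#' Angular field of illumination from spot diameter and working distance
#'
#' A fiber bundle's illumination cone is characterized by shining it on a flat
#' target and measuring the illuminated spot diameter at a known working
#' distance. The full cone angle (angular field of illumination, AFOI) is then
#' `2 * atan(SD / (2 * WD))`.
#'
#' @param spot_diameter Illuminated spot diameter in mm (> 0).
#' @param working_distance Distance from the probe tip to the target in mm
#'   (> 0).
#' @return The full illumination cone angle in degrees, in (0, 180).
#' @examples
#' compute_afoi(20, 13.03)  # ~75 degrees
#' @seealso [min_working_distance()] for the inverse computation.
#' @export
compute_afoi <- function(spot_diameter, working_distance) {
  check_positive(spot_diameter, "spot_diameter")
  check_positive(working_distance, "working_distance")
  2 * atan(spot_diameter / (2 * working_distance)) * 180 / pi
}

#' Minimum working distance to illuminate a target of a given size
#'
#' Given the illumination cone angle, the closest probe-tip distance at which
#' the illuminated spot still covers a target of diameter `d` is
#' `d / (2 * tan(AFOI / 2))`. For a 20 mm target and a 75 degree cone this is
#' about 13 mm.
#'
#' @param target_diameter Target (e.g. lesion) diameter in mm (> 0).
#' @param afoi Full illumination cone angle in degrees, in (0, 180).
#' @return Minimum working distance in mm.
#' @examples
#' min_working_distance(20, 75)
#' @export
min_working_distance <- function(target_diameter, afoi) {
  check_positive(target_diameter, "target_diameter")
  check_number(afoi, "afoi", function(v) v > 0 & v < 180,
               "not an angle in (0, 180) degrees")
  target_diameter / (2 * tan(afoi / 2 * pi / 180))
}

#' Michelson contrast of an imaged line-pair pattern
#'
#' Contrast transfer is measured on bar-target images (e.g. a USAF 1951
#' resolution target) from the cross-sectional maximum and minimum grayscale
#' intensities of a line-pair group: `(i_max - i_min) / (i_max + i_min)`.
#'
#' @param i_max Maximum grayscale intensity across the line pair (>= i_min).
#' @param i_min Minimum grayscale intensity (>= 0).
#' @return Contrast in \[0, 1\].
#' @examples
#' michelson_ctf(158, 92)
#' @export
michelson_ctf <- function(i_max, i_min) {
  check_number(i_max, "i_max", function(v) v >= 0, "negative")
  check_number(i_min, "i_min", function(v) v >= 0, "negative")
  if (i_min > i_max) stop("`i_min` exceeds `i_max`", call. = FALSE)
  if (i_max + i_min == 0) {
    stop("contrast undefined: i_max + i_min is zero", call. = FALSE)
  }
  (i_max - i_min) / (i_max + i_min)
}

#' Minimum resolvable object size from a line-pair spatial frequency
#'
#' The smallest resolvable object is taken as half the line-pair period at the
#' limiting spatial frequency: `1000 / (2 * f)` micrometers for `f` in line
#' pairs per mm.
#'
#' @param spatial_frequency Spatial frequency in line pairs per mm (> 0).
#' @return Object size in micrometers.
#' @examples
#' min_resolvable_object(3.763)  # ~133 um
#' @export
min_resolvable_object <- function(spatial_frequency) {
  check_positive(spatial_frequency, "spatial_frequency")
  1000 / (2 * spatial_frequency)
}

#' Fluorescence signal-to-noise ratio against a fluorophore-free control
#'
#' SNR for a fluorescence sensitivity test: the mean intensity of the signal
#' region of interest minus the mean of a matched control region, divided by
#' the standard deviation of the control region.
#'
#' @param signal_mean Mean pixel intensity of the fluorescing ROI.
#' @param control_mean Mean pixel intensity of the control ROI.
#' @param control_sd Standard deviation of the control ROI intensities (> 0).
#' @return Dimensionless SNR; 0 when signal equals control, negative when the
#'   signal falls below the control mean.
#' @examples
#' fluorescence_snr(120, 20, 10)  # 10: signal ten times the noise
#' @export
fluorescence_snr <- function(signal_mean, control_mean, control_sd) {
  check_number(signal_mean, "signal_mean")
  check_number(control_mean, "control_mean")
  check_positive(control_sd, "control_sd")
  (signal_mean - control_mean) / control_sd
}

#' Optical power attenuation in decibels
#'
#' `10 * log10(power_in / power_out)`. Additive over cascaded stages:
#' the attenuation a -> c equals the sum of a -> b and b -> c.
#'
#' @param power_in Input power in mW (> 0).
#' @param power_out Output power in mW (> 0), same units as `power_in`.
#' @return Attenuation in dB (0 when the powers are equal).
#' @examples
#' attenuation_db(1000, 52)  # 1 W source, 52 mW at the probe tip: 12.84 dB
#' @export
attenuation_db <- function(power_in, power_out) {
  check_positive(power_in, "power_in")
  check_positive(power_out, "power_out")
  10 * log10(power_in / power_out)
}

#' Fit a contrast transfer curve and locate the resolution limit
#'
#' Fits contrast measurements against spatial frequency by ordinary least
#' squares and finds the frequency at which the fitted line crosses the
#' Rayleigh-criterion contrast limit (by convention ~26.4%). The fit must be
#' decreasing for the limit to exist.
#'
#' @param spatial_frequency Spatial frequencies in line pairs per mm.
#' @param ctf Measured contrast values in \[0, 1\], same length.
#' @param contrast_limit Contrast at the resolution limit; default 0.264.
#' @return A list with `slope`, `intercept`, `r_squared`,
#'   `limit_frequency` (lp/mm at the contrast limit) and `min_object_um`
#'   (the corresponding minimum resolvable object size).
#' @examples
#' f <- c(1, 1.5, 2, 2.5, 3, 3.5)
#' ctf_fit(f, 0.9 - 0.17 * f)
#' @export
ctf_fit <- function(spatial_frequency, ctf, contrast_limit = 0.264) {
  check_positive(spatial_frequency, "spatial_frequency")
  check_number(ctf, "ctf", function(v) v >= 0 & v <= 1, "outside [0, 1]")
  if (length(spatial_frequency) != length(ctf) || length(ctf) < 3) {
    stop("need >= 3 paired (frequency, ctf) measurements", call. = FALSE)
  }
  check_number(contrast_limit, "contrast_limit",
               function(v) v > 0 & v < 1, "outside (0, 1)")
  fit <- stats::lm(ctf ~ spatial_frequency)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) {
    stop("contrast does not decrease with frequency; no resolution limit",
         call. = FALSE)
  }
  limit_frequency <- (contrast_limit - intercept) / slope
  if (limit_frequency <= 0) {
    stop("fitted contrast is below the limit at all frequencies",
         call. = FALSE)
  }
  r_squared <- 1 - sum(stats::resid(fit)^2) / sum((ctf - mean(ctf))^2)
  list(
    slope = slope,
    intercept = intercept,
    r_squared = r_squared,
    contrast_limit = contrast_limit,
    limit_frequency = limit_frequency,
    min_object_um = min_resolvable_object(limit_frequency)
  )
}
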