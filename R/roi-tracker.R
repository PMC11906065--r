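# Mean-intensity tracking of a pre-selected ROI and perfusion curve features.

#' Track mean fluorescence intensity of a region of interest
#'
#' The single-ROI workflow: isolate the fluorescence channel, average its
#' intensity over the ROI pixels frame by frame, and summarize the resulting
#' perfusion curve with simple wash-in/wash-out features. Features are
#' computed on a smoothed copy of the trace (centered moving average,
#' default 5 frames; set `smooth_window = 1` to disable).
#'
#' @param stack A [video_stack()].
#' @param roi An [roi_rect()]/[roi_polygon()], or a 0/1 mask matrix.
#' @param strategy,channel Channel isolation controls, as in
#'   [isolate_fluorescence_channel()].
#' @param smooth_window Moving-average window in frames (odd; default 5).
#' @return An object of class `perfusion_trace`: `times`, `values` (raw
#'   per-frame ROI means), `smoothed`, and `features` (see
#'   [perfusion_features()]).
#' @export
track_roi <- function(stack, roi, strategy = c("auto", "fixed"),
                      channel = 1L, smooth_window = 5L) {
  stopifnot(inherits(stack, "video_stack"))
  chan <- isolate_fluorescence_channel(stack, strategy = match.arg(strategy),
                                       channel = channel)
  d <- dim(chan$frames)
  mask <- if (inherits(roi, "roi_spec")) roi_mask(roi, d[1:2]) else roi
  validate_mask(mask)
  if (!identical(dim(mask), d[1:2])) {
    stop("ROI dimensions do not match the video", call. = FALSE)
  }
  lin <- which(mask == 1L)
  if (length(lin) == 0) stop("ROI selects no pixels", call. = FALSE)
  values <- vapply(seq_len(d[4]), function(t) {
    f <- chan$frames[, , 1, t]
    mean(f[lin])
  }, numeric(1))
  times <- frame_times(chan)
  smoothed <- moving_average(values, smooth_window)
  structure(
    list(
      times = times,
      values = values,
      smoothed = smoothed,
      features = perfusion_features(times, smoothed),
      channel = attr(chan, "channel"),
      n_pixels = length(lin)
    ),
    class = "perfusion_trace"
  )
}

#' @export
print.perfusion_trace <- function(x, ...) {
  f <- x$features
  cat(sprintf(
    "<perfusion_trace> %d frames, %d px; peak %.1f @ %.2f s, wash-in slope %.2f/s, washout rate %s/s\n",
    length(x$values), x$n_pixels, f$peak_value, f$time_to_peak,
    f$wash_in_slope, format(round(f$washout_rate, 4))
  ))
  invisible(x)
}

#' Wash-in / wash-out features of a perfusion curve
#'
#' Extracts four descriptors of an ICG time-intensity curve:
#' \describe{
#'   \item{time_to_peak}{Time of the curve maximum, in seconds.}
#'   \item{peak_value}{The maximum intensity.}
#'   \item{wash_in_slope}{Mean rise rate over the 10-90% rise interval
#'     (intensity/s), with the crossing times interpolated between frames.}
#'   \item{washout_rate}{Decay constant (1/s) from a log-linear fit of
#'     `value - baseline` over the tail, starting where the curve first
#'     drops below `tail_start_fraction` of the peak (above baseline).
#'     `NA` when fewer than 5 usable tail points exist.}
#' }
#' The baseline is the trace minimum (the pre-arrival plateau for a curve
#' observed from before bolus arrival).
#'
#' @param times Time stamps in seconds.
#' @param values Intensity values (typically the smoothed ROI trace).
#' @param tail_start_fraction Relative height (of peak above baseline) at
#'   which the washout fit window begins; default 0.7.
#' @return A list with the four features plus `baseline`.
#' @export
perfusion_features <- function(times, values, tail_start_fraction = 0.7) {
  if (length(times) != length(values)) {
    stop("times and values differ in length", call. = FALSE)
  }
  peak_idx <- which.max(values)
  peak_value <- values[peak_idx]
  baseline <- min(values)
  height <- peak_value - baseline

  if (height <= 0) {
    return(list(time_to_peak = times[peak_idx], peak_value = peak_value,
                wash_in_slope = 0, washout_rate = NA_real_,
                baseline = baseline))
  }

  # 10-90% rise interval, linearly interpolated between samples
  rel <- (values - baseline) / height
  cross_time <- function(level) {
    i <- which(rel[seq_len(peak_idx)] >= level)[1]
    if (is.na(i) || i == 1) return(times[1])
    frac <- (level - rel[i - 1]) / (rel[i] - rel[i - 1])
    times[i - 1] + frac * (times[i] - times[i - 1])
  }
  t10 <- cross_time(0.1)
  t90 <- cross_time(0.9)
  wash_in_slope <- if (t90 > t10) 0.8 * height / (t90 - t10) else NA_real_

  # log-linear washout fit on the decaying tail
  after <- seq(peak_idx, length(values))
  start_rel <- which(rel[after] <= tail_start_fraction)[1]
  washout_rate <- NA_real_
  if (!is.na(start_rel)) {
    tail_idx <- after[start_rel]:length(values)
    usable <- tail_idx[rel[tail_idx] > 0.02]  # keep log well away from 0
    if (length(usable) >= 5) {
      fit <- stats::lm(log(values[usable] - baseline) ~ times[usable])
      washout_rate <- -unname(stats::coef(fit)[2])
    }
  }

  list(time_to_peak = times[peak_idx], peak_value = peak_value,
       wash_in_slope = wash_in_slope, washout_rate = washout_rate,
       baseline = baseline)
}
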