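# Stage (1): channel isolation, thresholding, time-series extraction.

#' Isolate the fluorescence-carrying channel of a color video
#'
#' On single-color-sensor cameras the near-infrared ICG emission leaks
#' predominantly into one RGB channel (typically red). The channel is either
#' fixed explicitly or auto-selected as the one with the largest total
#' per-pixel temporal variance, i.e. the channel carrying the most intensity
#' dynamics. Grayscale conversion is the isolation itself: no luma mixing is
#' applied, as blending channels would dilute the fluorescence signal.
#'
#' @param stack A [video_stack()]. Single-channel input is returned as is.
#' @param strategy `"auto"` (temporal-variance argmax) or `"fixed"`.
#' @param channel Channel index (1..3) used when `strategy = "fixed"`.
#' @return A single-channel `video_stack`; the chosen channel index is
#'   attached as attribute `"channel"`.
#' @export
isolate_fluorescence_channel <- function(stack,
                                         strategy = c("auto", "fixed"),
                                         channel = 1L) {
  stopifnot(inherits(stack, "video_stack"))
  strategy <- match.arg(strategy)
  d <- dim(stack$frames)
  if (d[3] == 1L) {
    attr(stack, "channel") <- 1L
    return(stack)
  }
  if (strategy == "fixed") {
    ch <- as.integer(channel)
    if (ch < 1L || ch > d[3]) stop("channel index out of range", call. = FALSE)
  } else {
    ch <- which.max(vapply(seq_len(d[3]), function(c) {
      channel_temporal_variance(stack$frames, c)
    }, numeric(1)))
  }
  out <- video_stack(stack$frames[, , ch, , drop = FALSE],
                     frame_rate = stack$frame_rate,
                     bit_depth = stack$bit_depth)
  attr(out, "channel") <- ch
  out
}

# Sum over pixels of the per-pixel temporal variance of one channel,
# accumulated frame by frame to avoid materializing a float copy.
channel_temporal_variance <- function(frames, ch) {
  d <- dim(frames)
  t_n <- d[4]
  s1 <- matrix(0, d[1], d[2])
  s2 <- matrix(0, d[1], d[2])
  for (t in seq_len(t_n)) {
    f <- frames[, , ch, t]
    s1 <- s1 + f
    s2 <- s2 + f * f
    gc_every(t)
  }
  sum(s2 - s1 * s1 / t_n) / (t_n - 1)
}

# Per-pixel temporal statistic of a single-channel stack.
temporal_statistic <- function(stack, statistic = c("max", "mean", "range")) {
  statistic <- match.arg(statistic)
  d <- dim(stack$frames)
  stopifnot(d[3] == 1L)
  acc_max <- stack$frames[, , 1, 1] * 1.0
  acc_min <- acc_max
  acc_sum <- acc_max
  for (t in 2:d[4]) {
    f <- stack$frames[, , 1, t]
    if (statistic != "mean") acc_max <- pmax(acc_max, f)
    if (statistic == "range") acc_min <- pmin(acc_min, f)
    if (statistic == "mean") acc_sum <- acc_sum + f
    gc_every(t)
  }
  switch(statistic,
         max = acc_max,
         mean = acc_sum / d[4],
         range = acc_max - acc_min)
}

#' Threshold foreground pixels by a temporal intensity statistic
#'
#' Discards image background and areas of non-dynamic fluorescence: a pixel
#' is foreground when its per-pixel temporal statistic strictly exceeds the
#' threshold. The default statistic is the maximum over time (which keeps
#' late-arriving wash-in pixels); `mean` and `range` (peak-to-peak) are
#' alternatives. The threshold is given either as an absolute intensity or as
#' a fraction of the dynamic range (default 0.2, bit-depth independent).
#'
#' @param stack A single-channel [video_stack()].
#' @param threshold Absolute intensity threshold; overrides `fraction`.
#' @param fraction Threshold as a fraction of `2^bit_depth - 1`; default 0.2.
#' @param statistic Per-pixel temporal statistic to threshold.
#' @return A 0/1 integer foreground mask with attributes `"threshold"` and
#'   `"statistic"`.
#' @export
threshold_foreground <- function(stack, threshold = NULL, fraction = 0.2,
                                 statistic = c("max", "mean", "range")) {
  stopifnot(inherits(stack, "video_stack"))
  statistic <- match.arg(statistic)
  if (is.null(threshold)) {
    check_number(fraction, "fraction", function(v) v >= 0 & v <= 1,
                 "outside [0, 1]")
    threshold <- fraction * max_intensity(stack$bit_depth)
  }
  stat <- temporal_statistic(stack, statistic)
  mask <- matrix(as.integer(stat > threshold), nrow(stat), ncol(stat))
  if (sum(mask) == 0) {
    stop("threshold excludes every pixel: no foreground remains",
         call. = FALSE)
  }
  attr(mask, "threshold") <- threshold
  attr(mask, "statistic") <- statistic
  mask
}

#' Extract per-pixel intensity time-series for foreground pixels
#'
#' The working representation of the margination algorithm: each foreground
#' pixel's full intensity trace. Coordinates are enumerated in row-major
#' order (row 1 left to right, then row 2, ...).
#'
#' @param stack A single-channel [video_stack()].
#' @param mask A 0/1 matrix matching the frame dimensions.
#' @return An object of class `pixel_ts`: a list with `coords` (N x 2 integer
#'   matrix of 1-based `(row, col)`), `traces` (N x T numeric matrix) and
#'   `frame_rate`.
#' @export
extract_timeseries <- function(stack, mask) {
  stopifnot(inherits(stack, "video_stack"))
  d <- dim(stack$frames)
  stopifnot(d[3] == 1L)
  validate_mask(mask)
  if (!identical(dim(mask), d[1:2])) {
    stop("mask dimensions do not match the video", call. = FALSE)
  }
  w <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty mask: no foreground pixels", call. = FALSE)
  ord <- order(w[, 1], w[, 2])
  coords <- w[ord, , drop = FALSE]
  dimnames(coords) <- list(NULL, c("row", "col"))
  lin <- (coords[, 2] - 1L) * d[1] + coords[, 1]
  traces <- matrix(0, nrow(coords), d[4])
  for (t in seq_len(d[4])) {
    f <- stack$frames[, , 1, t]
    traces[, t] <- f[lin]
    gc_every(t)
  }
  structure(
    list(coords = coords, traces = traces, frame_rate = stack$frame_rate),
    class = "pixel_ts"
  )
}

#' @export
print.pixel_ts <- function(x, ...) {
  cat(sprintf("<pixel_ts> %d pixels x %d frames @ %g fps\n",
              nrow(x$traces), ncol(x$traces), x$frame_rate))
  invisible(x)
}
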