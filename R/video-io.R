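#' Construct a video stack
#'
#' The package's in-memory video container: a 4-D intensity array with frame
#' rate and bit depth. Intensities are stored in native units
#' (0..`2^bit_depth - 1`); storage mode may be integer (memory-friendly) or
#' double. Pixel coordinates are 1-based `(row, col)` with the origin at the
#' top-left, and the frame at index `t` has timestamp `(t - 1) / frame_rate`
#' seconds.
#'
#' @param frames Array of dimensions `H x W x C x T` (channels `C` in
#'   \{1, 3\}), or `H x W x T` which is treated as single-channel.
#' @param frame_rate Frames per second (> 0).
#' @param bit_depth Bits per sample, 8 or 16.
#' @return An object of class `video_stack`: a list with elements `frames`,
#'   `frame_rate`, `bit_depth`.
#' @examples
#' v <- video_stack(array(0L, c(8, 8, 1, 2)), frame_rate = 30)
#' dim(v$frames)
#' @export
video_stack <- function(frames, frame_rate, bit_depth = 8L) {
  if (!is.array(frames)) stop("`frames` must be an array", call. = FALSE)
  if (length(dim(frames)) == 3L) {
    dim(frames) <- c(dim(frames)[1:2], 1L, dim(frames)[3])
  }
  d <- dim(frames)
  if (length(d) != 4L) {
    stop("`frames` must have dimensions H x W x C x T", call. = FALSE)
  }
  if (!d[3] %in% c(1L, 3L)) stop("channel count must be 1 or 3", call. = FALSE)
  if (d[4] < 2L) stop("a video needs at least 2 frames", call. = FALSE)
  if (d[1] < 8L || d[2] < 8L) stop("frames must be at least 8 x 8", call. = FALSE)
  check_positive(frame_rate, "frame_rate")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  # min()/max() rather than range(): range.default concatenates its
  # arguments, which would copy a multi-GB frame array
  if (min(frames) < 0 || max(frames) > 2^bit_depth - 1) {
    stop("intensities outside the bit-depth range", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = frame_rate, bit_depth = bit_depth),
    class = "video_stack"
  )
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<video_stack> %d x %d px, %d channel(s), %d frames @ %g fps, %d-bit\n",
    d[1], d[2], d[3], d[4], x$frame_rate, x$bit_depth
  ))
  invisible(x)
}

#' Number of frames in a video stack
#' @param stack A [video_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[4]

#' Frame timestamps of a video stack
#' @param stack A [video_stack()].
#' @return Numeric vector of length T; the first frame is at 0 s.
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) / stack$frame_rate
}

max_intensity <- function(bit_depth) 2^bit_depth - 1

#' Read a fluorescence video from a frame stack
#'
#' Supported containers are multi-page TIFF files and directories of
#' numbered PNG frames (ordered by the last number in each file name).
#' Compressed video containers (AVI/MP4) are not supported; decode them to a
#' frame stack with an external tool first.
#'
#' @param path A `.tif`/`.tiff` file or a directory of `.png` frames.
#' @param frame_rate Frames per second to attach to the stack (frame stacks
#'   carry no timing metadata); default 30.
#' @param bit_depth Bits per sample; default 8. TIFF pages holding values
#'   above 255 force 16.
#' @return A [video_stack()].
#' @export
read_video <- function(path, frame_rate = 30, bit_depth = 8L) {
  if (grepl("\\.(avi|mp4|mov|mkv)$", tolower(path))) {
    stop("compressed video containers are not supported; ",
         "decode to a multi-page TIFF or a PNG frame directory first",
         call. = FALSE)
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
    if (length(files) < 2) stop("need at least 2 PNG frames", call. = FALSE)
    num <- vapply(basename(files), function(f) {
      m <- regmatches(f, gregexpr("[0-9]+", f))[[1]]
      if (length(m) == 0) NA_real_ else as.numeric(m[length(m)])
    }, numeric(1))
    if (anyNA(num)) stop("PNG frame names must carry a frame number", call. = FALSE)
    files <- files[order(num)]
    pages <- lapply(files, function(f) {
      p <- png::readPNG(f)
      if (length(dim(p)) == 3 && dim(p)[3] == 4) p <- p[, , 1:3, drop = FALSE]
      p
    })
    scale <- max_intensity(bit_depth)
    frames <- stack_pages(lapply(pages, function(p) round(p * scale)))
  } else if (grepl("\\.tiff?$", tolower(path))) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2) stop("need at least 2 TIFF pages", call. = FALSE)
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits) && bits %in% c(8L, 16L)) bit_depth <- as.integer(bits)
    scale <- max_intensity(bit_depth)
    frames <- stack_pages(lapply(pages, function(p) round(p * scale)))
  } else {
    stop("unsupported video path: ", path, call. = FALSE)
  }
  video_stack(frames, frame_rate = frame_rate, bit_depth = bit_depth)
}

# Bind a list of H x W (x C) pages into an H x W x C x T array.
stack_pages <- function(pages) {
  d1 <- dim(pages[[1]])
  same <- vapply(pages, function(p) identical(dim(p), d1), logical(1))
  if (!all(same)) stop("frames differ in shape", call. = FALSE)
  h <- d1[1]; w <- d1[2]
  ch <- if (length(d1) == 3) d1[3] else 1L
  arr <- array(0, c(h, w, ch, length(pages)))
  for (t in seq_along(pages)) {
    arr[, , , t] <- pages[[t]]
  }
  arr
}

#' Write a video stack to disk
#'
#' @param stack A [video_stack()].
#' @param path Output path: a `.tif`/`.tiff` file (multi-page, lossless) or a
#'   directory (PNG frames `frame_0001.png`, ...).
#' @param format `"tiff"` or `"png_dir"`; inferred from `path` by default.
#' @return `path`, invisibly.
#' @export
write_video <- function(stack, path, format = NULL) {
  stopifnot(inherits(stack, "video_stack"))
  if (is.null(format)) {
    format <- if (grepl("\\.tiff?$", tolower(path))) "tiff" else "png_dir"
  }
  if (grepl("\\.(avi|mp4|mov|mkv)$", tolower(path))) {
    stop("compressed video containers are not supported", call. = FALSE)
  }
  scale <- max_intensity(stack$bit_depth)
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[4]), function(t) {
    p <- stack$frames[, , , t, drop = TRUE]
    if (d[3] == 1L) dim(p) <- d[1:2]
    p / scale
  })
  if (format == "tiff") {
    tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                    compression = "none")
  } else if (format == "png_dir") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (t in seq_along(pages)) {
      png::writePNG(pages[[t]], file.path(path, sprintf("frame_%04d.png", t)))
    }
  } else {
    stop("unknown format: ", format, call. = FALSE)
  }
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are `H x W` matrices over \{0, 1\} in memory. On disk they are
#' either PNG images (0 background / 255 foreground, the viewable convention)
#' or plain-text matrices of whitespace-separated 0/1 values, chosen by file
#' extension (`.png` vs anything else).
#'
#' @param path File path.
#' @param grid A 0/1 matrix.
#' @return `read_mask` returns a 0/1 integer matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", tolower(path))) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    grid <- matrix(as.integer(img > 0.5), nrow(img), ncol(img))
  } else {
    rows <- strsplit(trimws(readLines(path)), "[[:space:]]+")
    rows <- rows[lengths(rows) > 0]
    width <- length(rows[[1]])
    if (!all(lengths(rows) == width)) {
      stop("ragged mask rows in ", path, call. = FALSE)
    }
    grid <- matrix(as.integer(unlist(rows)), length(rows), width, byrow = TRUE)
  }
  validate_mask(grid)
  grid
}

#' @rdname read_mask
#' @export
write_mask <- function(grid, path) {
  validate_mask(grid)
  if (grepl("\\.png$", tolower(path))) {
    png::writePNG(matrix(as.numeric(grid), nrow(grid), ncol(grid)), path)
  } else {
    writeLines(apply(grid, 1, paste, collapse = " "), path)
  }
  invisible(path)
}

validate_mask <- function(grid) {
  if (!is.matrix(grid) || !all(grid %in% c(0L, 1L))) {
    stop("a mask must be a matrix with values in {0, 1}", call. = FALSE)
  }
  invisible(grid)
}

#' Rectangular and polygonal regions of interest
#'
#' ROI coordinates are 1-based pixel positions `(row, col)`; rectangle bounds
#' are inclusive. Polygons are closed automatically and rasterized with the
#' even-odd rule against pixel centers.
#'
#' @param row0,col0,row1,col1 Inclusive rectangle corners.
#' @param vertices Two-column matrix of polygon vertices `(row, col)`.
#' @return An object of class `roi_spec`.
#' @examples
#' roi_rect(10, 10, 20, 30)
#' @export
roi_rect <- function(row0, col0, row1, col1) {
  check_positive(row0, "row0"); check_positive(col0, "col0")
  if (row1 < row0 || col1 < col0) stop("empty rectangle", call. = FALSE)
  structure(list(type = "rect",
                 row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1)),
            class = "roi_spec")
}

#' @rdname roi_rect
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("a polygon needs >= 3 (row, col) vertices", call. = FALSE)
  }
  structure(list(type = "polygon", vertices = vertices), class = "roi_spec")
}

#' Rasterize an ROI to a binary mask
#'
#' @param roi An [roi_rect()] or [roi_polygon()].
#' @param dim Frame dimensions `c(H, W)`.
#' @return A 0/1 integer matrix of the requested dimensions.
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "roi_spec"))
  h <- dim[1]; w <- dim[2]
  mask <- matrix(0L, h, w)
  if (roi$type == "rect") {
    if (roi$row1 > h || roi$col1 > w) stop("ROI outside frame", call. = FALSE)
    mask[roi$row0:roi$row1, roi$col0:roi$col1] <- 1L
  } else {
    v <- roi$vertices
    if (any(v[, 1] < 1 | v[, 1] > h | v[, 2] < 1 | v[, 2] > w)) {
      stop("ROI outside frame", call. = FALSE)
    }
    py <- rep(seq_len(h), times = w)   # rows
    px <- rep(seq_len(w), each = h)    # cols
    inside <- rep(FALSE, h * w)
    n <- nrow(v)
    jj <- c(n, seq_len(n - 1))
    for (i in seq_len(n)) {
      y1 <- v[i, 1]; x1 <- v[i, 2]
      y2 <- v[jj[i], 1]; x2 <- v[jj[i], 2]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
    mask[inside] <- 1L
  }
  if (sum(mask) == 0) stop("ROI has empty interior", call. = FALSE)
  mask
}

#' Read and write ROI specifications as JSON
#'
#' @param roi An `roi_spec`.
#' @param path JSON file path.
#' @return `read_roi` returns an `roi_spec`; `write_roi` returns `path`
#'   invisibly.
#' @export
read_roi <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$type, "rect")) {
    roi_rect(x$row0, x$col0, x$row1, x$col1)
  } else if (identical(x$type, "polygon")) {
    roi_polygon(x$vertices)
  } else {
    stop("unknown ROI type in ", path, call. = FALSE)
  }
}

#' @rdname read_roi
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_spec"))
  jsonlite::write_json(unclass(roi), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write intensity time-series as CSV
#'
#' Columns: `frame_index` (1-based), `time_s` (`(frame_index - 1) /
#' frame_rate`), `value`.
#'
#' @param values Numeric vector of per-frame values.
#' @param path CSV file path.
#' @param frame_rate Frames per second used to derive `time_s`.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a data.frame with the three columns above.
#' @export
write_timeseries <- function(values, path, frame_rate) {
  check_positive(frame_rate, "frame_rate")
  df <- data.frame(
    frame_index = seq_along(values),
    time_s = (seq_along(values) - 1) / frame_rate,
    value = as.numeric(values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame_index", "time_s", "value") %in% names(df))) {
    stop("not a time-series CSV: ", path, call. = FALSE)
  }
  df
}
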