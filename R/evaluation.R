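# Jaccard-index evaluation of delineated regions against reference masks.

#' Jaccard index of two binary masks
#'
#' `|A intersect B| / |A union B|`: 1 for identical non-empty masks, 0 for
#' disjoint masks. Undefined (an error) when both masks are empty.
#'
#' @param a,b 0/1 matrices of equal dimensions.
#' @return A number in \[0, 1\].
#' @examples
#' m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L
#' jaccard(m, m)
#' @export
jaccard <- function(a, b) {
  validate_mask(a)
  validate_mask(b)
  if (!identical(dim(a), dim(b))) {
    stop("masks differ in shape", call. = FALSE)
  }
  union <- sum(a == 1L | b == 1L)
  if (union == 0) {
    stop("Jaccard undefined: both masks are empty", call. = FALSE)
  }
  sum(a == 1L & b == 1L) / union
}

#' Batch Jaccard evaluation of margination results against reference masks
#'
#' Compares each video's two predicted chamber masks with its two reference
#' masks. Because the algorithm's chamber numbering is arbitrary, the
#' chamber-to-reference correspondence is resolved per video by the pairing
#' (identity or swapped) that maximizes the total Jaccard; an exact tie keeps
#' the identity pairing with a warning.
#'
#' @param predictions List of [marginate()] results (or lists of two 0/1
#'   masks), one per video.
#' @param references List of lists of two reference 0/1 masks, index-aligned
#'   with `predictions`.
#' @param video_ids Optional video identifiers; defaults to `1:n`.
#' @return An object of class `jaccard_report`: `per_chamber` (data.frame
#'   with columns `video`, `chamber`, `jaccard`) and summary `mean`, `min`,
#'   `max` over all entries.
#' @export
evaluate_batch <- function(predictions, references, video_ids = NULL) {
  if (length(predictions) != length(references)) {
    stop("predictions and references differ in length", call. = FALSE)
  }
  n <- length(predictions)
  if (n == 0) stop("nothing to evaluate", call. = FALSE)
  video_ids <- video_ids %||% seq_len(n)

  # Jaccard that tolerates an empty *prediction* (scored 0): an algorithm
  # may legitimately find nothing where the reference marks a chamber.
  j0 <- function(a, b) {
    if (sum(a) + sum(b) == 0) {
      stop("Jaccard undefined: both masks are empty", call. = FALSE)
    }
    sum(a == 1L & b == 1L) / sum(a == 1L | b == 1L)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pred <- predictions[[i]]
    p <- if (inherits(pred, "margination_result")) {
      list(pred$chamber1_mask, pred$chamber2_mask)
    } else {
      pred
    }
    r <- references[[i]]
    if (length(p) != 2 || length(r) != 2) {
      stop("each video needs exactly 2 predicted and 2 reference masks",
           call. = FALSE)
    }
    identity_total <- j0(p[[1]], r[[1]]) + j0(p[[2]], r[[2]])
    swapped_total <- j0(p[[1]], r[[2]]) + j0(p[[2]], r[[1]])
    if (identity_total == swapped_total && sum(p[[1]]) + sum(p[[2]]) > 0) {
      warning("pairing ambiguity for video ", video_ids[i],
              ": keeping identity pairing", call. = FALSE)
    }
    if (swapped_total > identity_total) r <- r[c(2, 1)]
    rows[[i]] <- data.frame(
      video = rep(video_ids[i], 2),
      chamber = 1:2,
      jaccard = c(j0(p[[1]], r[[1]]), j0(p[[2]], r[[2]]))
    )
  }
  per_chamber <- do.call(rbind, rows)
  structure(
    list(
      per_chamber = per_chamber,
      mean = mean(per_chamber$jaccard),
      min = min(per_chamber$jaccard),
      max = max(per_chamber$jaccard)
    ),
    class = "jaccard_report"
  )
}

#' @export
print.jaccard_report <- function(x, ...) {
  cat(sprintf(
    "<jaccard_report> %d entries: mean %.3f (min %.3f, max %.3f)\n",
    nrow(x$per_chamber), x$mean, x$min, x$max
  ))
  invisible(x)
}
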