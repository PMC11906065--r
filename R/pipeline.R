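# End-to-end margination pipeline and the phantom reproduction study.

#' Run the full field-of-view margination pipeline on a video
#'
#' Chains the three algorithm stages: (1) fluorescence channel isolation and
#' intensity thresholding, (2) PCA reduction and k-means clustering of the
#' foreground pixel time-series with selection of the two clusters of
#' highest accumulated fluorescence, (3) per-pixel NCC maps against the two
#' selected cluster-center curves and margination of the signed NCC
#' difference into two region masks and a boundary band.
#'
#' @param video A [video_stack()].
#' @param seed Integer seed for the clustering stage (required).
#' @param strategy,channel Channel isolation controls
#'   ([isolate_fluorescence_channel()]).
#' @param threshold,fraction,statistic Foreground thresholding controls
#'   ([threshold_foreground()]).
#' @param n_components,var_target,max_components PCA controls
#'   ([reduce_pca()]).
#' @param k,n_restarts Clustering controls ([cluster_kmeans()]).
#' @param n_select Number of chamber clusters selected; default 2.
#' @param epsilon,keep_largest_component Margination controls
#'   ([marginate()]).
#' @return An object of class `margination_pipeline`: `result` (the
#'   [marginate()] output), `maps`, `clustering`, `selected`, `pca`,
#'   `foreground`, `channel`.
#' @examples
#' \donttest{
#' ph <- generate_phantom(default_phantom_config(seed = 1))
#' out <- margination_pipeline(ph$video, seed = 0)
#' out$result
#' }
#' @export
margination_pipeline <- function(video, seed,
                                 strategy = c("auto", "fixed"), channel = 1L,
                                 threshold = NULL, fraction = 0.2,
                                 statistic = "max",
                                 n_components = NULL, var_target = 0.99,
                                 max_components = 10L,
                                 k = 4L, n_restarts = 10L, n_select = 2L,
                                 epsilon = 0.05,
                                 keep_largest_component = FALSE) {
  stopifnot(inherits(video, "video_stack"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  chan <- isolate_fluorescence_channel(video, strategy = match.arg(strategy),
                                       channel = channel)
  fg <- threshold_foreground(chan, threshold = threshold, fraction = fraction,
                             statistic = statistic)
  px <- extract_timeseries(chan, fg)
  invisible(gc(FALSE))
  pca <- reduce_pca(px, n_components = n_components, var_target = var_target,
                    max_components = max_components)
  invisible(gc(FALSE))
  clustering <- cluster_kmeans(pca, px, k = k, seed = seed,
                               n_restarts = n_restarts)
  selected <- select_chamber_clusters(clustering, n_select = n_select)
  maps <- ncc_maps(px, clustering$centers_ts[selected, , drop = FALSE],
                   dim(chan$frames)[1:2])
  result <- marginate(maps, epsilon = epsilon,
                      keep_largest_component = keep_largest_component)
  structure(
    list(
      result = result,
      maps = maps,
      clustering = clustering,
      selected = selected,
      pca = pca,
      foreground = fg,
      channel = attr(chan, "channel")
    ),
    class = "margination_pipeline"
  )
}

#' @export
print.margination_pipeline <- function(x, ...) {
  cat(sprintf(
    "<margination_pipeline> channel %d, %d foreground px, d = %d, k = %d, selected clusters %s\n",
    x$channel, sum(x$foreground), x$pca$n_components, x$clustering$k,
    paste(x$selected, collapse = ", ")
  ))
  print(x$result)
  invisible(x)
}

#' Phantom margination reproduction study
#'
#' Generates a batch of dual-chamber phantom videos (one per seed), runs the
#' full margination pipeline on each, and scores every delineated chamber
#' mask against its ground-truth mask with best-pairing Jaccard. This is the
#' package's desk-scale surrogate for a bench evaluation of the algorithm on
#' N captured videos.
#'
#' @param seeds Phantom noise seeds, one video per seed; default `0:8`
#'   (nine videos).
#' @param kmeans_seed Seed of the clustering stage; default 0.
#' @param config_fn Function mapping a seed to a [phantom_config()];
#'   default [default_phantom_config()].
#' @param verbose Print per-video progress.
#' @param ... Passed on to [margination_pipeline()].
#' @return A [evaluate_batch()] `jaccard_report` (18 entries for the default
#'   nine videos, two chambers each).
#' @export
phantom_margination_study <- function(seeds = 0:8, kmeans_seed = 0L,
                                      config_fn = default_phantom_config,
                                      verbose = FALSE, ...) {
  predictions <- vector("list", length(seeds))
  references <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    ph <- generate_phantom(config_fn(seeds[i]))
    references[[i]] <- ph$truth$chamber_masks
    # isolate the fluorescence channel up front and release the RGB frames:
    # full-resolution color video dominates the study's memory footprint
    chan <- isolate_fluorescence_channel(ph$video)
    rm(ph)
    gc(verbose = FALSE)
    out <- margination_pipeline(chan, seed = kmeans_seed, ...)
    predictions[[i]] <- out$result
    if (verbose) {
      message(sprintf("video seed %s: chamber px %d/%d, boundary %d",
                      format(seeds[i]), sum(out$result$chamber1_mask),
                      sum(out$result$chamber2_mask),
                      sum(out$result$boundary_mask)))
    }
    rm(chan, out)
    gc(verbose = FALSE)
  }
  evaluate_batch(predictions, references, video_ids = seeds)
}
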