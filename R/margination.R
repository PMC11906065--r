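# Stages (2)-(3): PCA reduction, k-means clustering, cluster selection,
# per-pixel NCC maps and NCC-difference margination.

#' Reduce pixel time-series by principal component analysis
#'
#' Projects the (column-centered) N x T trace matrix onto its top principal
#' axes, computed from the eigendecomposition of the T x T covariance matrix.
#' Component signs are fixed by convention (the largest-magnitude loading of
#' each component is positive) so the embedding is deterministic.
#'
#' @param x A `pixel_ts` object or an N x T numeric matrix.
#' @param n_components Number of components `d`; when `NULL`, the smaller of
#'   `max_components` and the number needed to reach `var_target` cumulative
#'   explained variance.
#' @param var_target Target cumulative explained-variance ratio; default 0.99.
#' @param max_components Upper cap on the automatic choice; default 10.
#' @return An object of class `pca_reduction`: `embedding` (N x d),
#'   `rotation` (T x d), `center` (length-T column means),
#'   `explained_variance` (ratios, all T), `n_components`.
#' @export
reduce_pca <- function(x, n_components = NULL, var_target = 0.99,
                       max_components = 10L) {
  traces <- if (inherits(x, "pixel_ts")) x$traces else as.matrix(x)
  n <- nrow(traces); t_n <- ncol(traces)
  if (n < 2 || t_n < 2) stop("need at least 2 pixels and 2 frames", call. = FALSE)
  mu <- colMeans(traces)
  xc <- traces - rep(mu, each = n)
  cv <- crossprod(xc) / (n - 1)
  ee <- eigen(cv, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  evr <- vals / sum(vals)
  if (is.null(n_components)) {
    d <- min(as.integer(max_components), which(cumsum(evr) >= var_target)[1])
  } else {
    d <- as.integer(n_components)
  }
  if (d < 1 || d >= t_n || d >= n) {
    stop("n_components must satisfy 1 <= d < min(N, T)", call. = FALSE)
  }
  rot <- ee$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(
      embedding = xc %*% rot,
      rotation = rot,
      center = mu,
      explained_variance = evr,
      n_components = d
    ),
    class = "pca_reduction"
  )
}

# k-means++ style seeding: first center uniform, then each subsequent center
# sampled with probability proportional to squared distance to the nearest
# chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    idx <- if (tot > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

#' Cluster reduced pixel time-series with k-means
#'
#' Runs Lloyd's k-means on the reduced embedding with k-means++ style
#' seeding, keeping the best of `n_restarts` runs by total within-cluster sum
#' of squares. Cluster-center time-series are computed as the per-cluster
#' mean of the ORIGINAL traces (not the PCA reconstruction), so the later
#' correlation stage is independent of the dimensionality reduction.
#'
#' @param embedding A `pca_reduction` or an N x d matrix.
#' @param traces The matching `pixel_ts` or N x T trace matrix.
#' @param k Number of clusters (>= 2); N must be at least `10 * k`.
#' @param seed Integer seed for the stochastic seeding (required: clustering
#'   is only reproducible with it).
#' @param n_restarts Independent seeded restarts; default 10.
#' @return An object of class `clustering_result`: `labels` (N, in 1..k),
#'   `centers_ts` (k x T), `auc` (accumulated fluorescence: sum over time of
#'   each center trace), `sizes`, `inertia`, `k`, `seed`.
#' @export
cluster_kmeans <- function(embedding, traces, k = 4L, seed, n_restarts = 10L) {
  x <- if (inherits(embedding, "pca_reduction")) embedding$embedding else as.matrix(embedding)
  tr <- if (inherits(traces, "pixel_ts")) traces$traces else as.matrix(traces)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- nrow(x)
  if (nrow(tr) != n) stop("embedding and traces disagree in N", call. = FALSE)
  if (n < 10L * k) stop("need at least 10 * k pixels to cluster", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducible clustering", call. = FALSE)

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      km <- tryCatch(
        suppressWarnings(
          stats::kmeans(x, centers = kmeanspp_init(x, k), iter.max = 100L,
                        algorithm = "Lloyd")
        ),
        error = function(e) NULL
      )
      if (is.null(km) || any(km$size == 0)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) {
    stop("k-means produced an empty cluster in every restart ",
         "(degenerate input?)", call. = FALSE)
  }
  labels <- best$cluster
  sizes <- tabulate(labels, k)
  centers_ts <- rowsum(tr, labels) / sizes
  structure(
    list(
      labels = labels,
      centers_ts = centers_ts,
      auc = rowSums(centers_ts),
      sizes = sizes,
      inertia = best$tot.withinss,
      k = k,
      seed = seed
    ),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d, sizes = %s, seed = %s\n",
              x$k, paste(x$sizes, collapse = "/"), format(x$seed)))
  invisible(x)
}

#' Select the chamber-representative clusters
#'
#' Chamber-representative clusters are those with the highest accumulated
#' fluorescence (area under the cluster-center curve). Ties are broken by the
#' lower cluster id.
#'
#' @param clustering A [cluster_kmeans()] result.
#' @param n_select Number of clusters to select; default 2.
#' @return Integer cluster ids in decreasing accumulated-fluorescence order.
#' @export
select_chamber_clusters <- function(clustering, n_select = 2L) {
  stopifnot(inherits(clustering, "clustering_result"))
  n_select <- as.integer(n_select)
  if (n_select > clustering$k) stop("n_select exceeds k", call. = FALSE)
  ord <- order(-clustering$auc, seq_along(clustering$auc))
  ord[seq_len(n_select)]
}

#' Normalized cross-correlation of two equal-length time-series
#'
#' `NCC = (1 / (T - 1)) * sum(((a - mean(a)) / sd(a)) * ((b - mean(b)) / sd(b)))`
#' with sample standard deviations (denominator `T - 1`, matching the
#' prefactor so that `ncc(a, a)` is exactly 1). Identical signals give 1,
#' negated signals -1, unrelated signals values near 0. The value is
#' invariant under positive affine rescaling of either argument.
#'
#' @param a,b Numeric vectors of equal length `T >= 2`, each non-constant.
#' @return A number in \[-1, 1\].
#' @examples
#' ncc(1:10, 1:10)       #  1
#' ncc(1:10, -(1:10))    # -1
#' @export
ncc <- function(a, b) {
  if (length(a) != length(b)) stop("signals differ in length", call. = FALSE)
  t_n <- length(a)
  if (t_n < 2) stop("need T >= 2", call. = FALSE)
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    stop("NCC undefined for a constant (zero-variance) signal", call. = FALSE)
  }
  sum(((a - mean(a)) / sa) * ((b - mean(b)) / sb)) / (t_n - 1)
}

#' Per-pixel NCC maps against two cluster-center time-series
#'
#' Correlates every foreground pixel's trace with each of the two selected
#' cluster-center curves, yielding two correlation images and their signed
#' difference. Pixels with zero temporal variance carry `NA` in all three
#' maps (the correlation is undefined there); non-foreground pixels are `NA`.
#'
#' @param px A `pixel_ts` from [extract_timeseries()].
#' @param centers_ts A 2 x T matrix of cluster-center traces (e.g. the
#'   selected rows of a [cluster_kmeans()] `centers_ts`).
#' @param frame_shape Frame dimensions `c(H, W)`.
#' @return An object of class `ncc_maps`: `ncc_c1`, `ncc_c2`, `ncc_diff`
#'   (H x W numeric matrices; `ncc_diff = ncc_c1 - ncc_c2`) and `foreground`
#'   (0/1 matrix of pixels where the maps are defined).
#' @export
ncc_maps <- function(px, centers_ts, frame_shape) {
  stopifnot(inherits(px, "pixel_ts"))
  centers_ts <- as.matrix(centers_ts)
  if (nrow(centers_ts) != 2) stop("exactly 2 cluster centers required", call. = FALSE)
  t_n <- ncol(px$traces)
  if (ncol(centers_ts) != t_n) stop("center length differs from traces", call. = FALSE)
  c_sd <- apply(centers_ts, 1, stats::sd)
  if (any(c_sd == 0)) stop("cluster center has zero variance", call. = FALSE)
  zc <- (centers_ts - rowMeans(centers_ts)) / c_sd

  cent <- px$traces - rowMeans(px$traces)
  sds <- sqrt(rowSums(cent^2) / (t_n - 1))
  vals <- cent %*% t(zc) / (sds * (t_n - 1))   # N x 2; NaN where sd == 0
  vals[sds == 0, ] <- NA_real_
  vals <- pmin(pmax(vals, -1), 1)

  h <- frame_shape[1]; w <- frame_shape[2]
  lin <- (px$coords[, 2] - 1L) * h + px$coords[, 1]
  m1 <- matrix(NA_real_, h, w); m1[lin] <- vals[, 1]
  m2 <- matrix(NA_real_, h, w); m2[lin] <- vals[, 2]
  fg <- matrix(0L, h, w)
  fg[lin[!is.na(vals[, 1])]] <- 1L
  structure(
    list(ncc_c1 = m1, ncc_c2 = m2, ncc_diff = m1 - m2, foreground = fg),
    class = "ncc_maps"
  )
}

#' Delineate perfusion regions from an NCC difference map
#'
#' Splits the foreground by the sign of `ncc_diff = ncc_c1 - ncc_c2`:
#' pixels correlating more with the first center (`ncc_diff > epsilon`) form
#' region 1, those correlating more with the second (`ncc_diff < -epsilon`)
#' form region 2, and the band `|ncc_diff| <= epsilon` is the boundary
#' between them. The three masks are disjoint and contained in the
#' foreground.
#'
#' @param maps An [ncc_maps()] result.
#' @param epsilon Half-width of the boundary band; default 0.05.
#' @param keep_largest_component If `TRUE`, each chamber mask is reduced to
#'   its largest 4-connected component (off by default).
#' @return An object of class `margination_result`: `chamber1_mask`,
#'   `chamber2_mask`, `boundary_mask` (0/1 integer matrices) and `epsilon`.
#' @export
marginate <- function(maps, epsilon = 0.05, keep_largest_component = FALSE) {
  stopifnot(inherits(maps, "ncc_maps"))
  check_number(epsilon, "epsilon", function(v) v >= 0, "negative")
  diffm <- maps$ncc_diff
  defined <- !is.na(diffm)
  as_mask <- function(sel) {
    m <- matrix(0L, nrow(diffm), ncol(diffm))
    m[defined & sel] <- 1L
    m
  }
  ch1 <- as_mask(diffm > epsilon)
  ch2 <- as_mask(diffm < -epsilon)
  bnd <- as_mask(abs(diffm) <= epsilon)
  if (keep_largest_component) {
    ch1 <- largest_component(ch1)
    ch2 <- largest_component(ch2)
  }
  structure(
    list(chamber1_mask = ch1, chamber2_mask = ch2, boundary_mask = bnd,
         epsilon = epsilon),
    class = "margination_result"
  )
}

#' @export
print.margination_result <- function(x, ...) {
  cat(sprintf(
    "<margination_result> chamber1: %d px, chamber2: %d px, boundary: %d px (epsilon = %g)\n",
    sum(x$chamber1_mask), sum(x$chamber2_mask), sum(x$boundary_mask),
    x$epsilon
  ))
  invisible(x)
}

# Keep only the largest 4-connected component of a binary mask.
largest_component <- function(mask) {
  idx <- which(mask == 1L)
  if (length(idx) <= 1) return(mask)
  h <- nrow(mask)
  id <- matrix(0L, h, ncol(mask))
  id[idx] <- seq_along(idx)
  # edges to the neighbor below and to the right, within the mask
  edges <- NULL
  down_ok <- (idx %% h) != 0L
  down <- idx[down_ok][mask[idx[down_ok] + 1L] == 1L]
  if (length(down)) edges <- rbind(edges, cbind(id[down], id[down + 1L]))
  right_ok <- idx + h <= length(mask)
  right <- idx[right_ok][mask[idx[right_ok] + h] == 1L]
  if (length(right)) edges <- rbind(edges, cbind(id[right], id[right + h]))
  g <- igraph::make_graph(if (is.null(edges)) integer(0) else t(edges),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[idx[keep]] <- 1L
  out
}
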