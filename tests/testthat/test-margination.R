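# Oracle: full eigendecomposition PCA on a small matrix, kept deliberately
# naive (direct covariance of centered data, no component cap).
pca_oracle_var <- function(x, d) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)$values
  sum(ev[seq_len(d)]) / sum(ev)
}

test_that("PCA reduction captures low-rank structure", {
  # rank-1 data: traces on a line in T-space reconstruct exactly from d = 1
  set.seed(1)
  base <- sin(seq(0, 3, length.out = 20))
  x <- outer(stats::runif(40, 0.5, 2), base)
  p <- reduce_pca(x, n_components = 1)
  recon <- p$embedding %*% t(p$rotation) + rep(p$center, each = nrow(x))
  expect_equal(recon, x, tolerance = 1e-10)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)

  # full-rank data: using all T components explains everything
  y <- matrix(rnorm(15 * 6), 15, 6)
  pf <- reduce_pca(y, n_components = 5)
  expect_equal(sum(pf$explained_variance[1:5]),
               pca_oracle_var(y, 5), tolerance = 1e-10)

  expect_error(reduce_pca(y, n_components = 6), "n_components")
})

test_that("PCA on two-family phantom traces is low dimensional", {
  ph <- generate_phantom(small_phantom_config(seed = 2))
  chan <- isolate_fluorescence_channel(ph$video)
  fg <- threshold_foreground(chan)
  px <- extract_timeseries(chan, fg)
  p <- reduce_pca(px, n_components = 2)
  expect_gte(sum(p$explained_variance[1:2]), 0.95)
  expect_equal(sum(p$explained_variance[1:2]),
               pca_oracle_var(px$traces, 2), tolerance = 1e-8)
})

test_that("k-means recovers well-separated clouds and is deterministic", {
  set.seed(9)
  n <- 60
  emb <- rbind(
    matrix(rnorm(2 * n, sd = 0.1), ncol = 2),
    matrix(rnorm(2 * n, sd = 0.1) + 10, ncol = 2)
  )
  truth <- rep(1:2, each = n)
  traces <- cbind(emb, emb)  # any T >= 2 stand-in traces
  cl <- cluster_kmeans(emb, traces, k = 2, seed = 123)
  # brute-force nearest-center oracle must agree with the labels
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_equal(agree, 1)
  centers <- rowsum(emb, cl$labels) / as.vector(table(cl$labels))
  d2 <- as.matrix(stats::dist(rbind(centers, emb)))[-(1:2), 1:2]
  expect_equal(unname(apply(d2, 1, which.min)), unname(cl$labels))

  cl2 <- cluster_kmeans(emb, traces, k = 2, seed = 123)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$centers_ts, cl2$centers_ts)

  # degenerate input: identical points cannot fill 2 clusters
  same <- matrix(1, 40, 2)
  expect_error(cluster_kmeans(same, same, k = 2, seed = 1), "empty cluster")
})

test_that("cluster centers are member means in original trace space", {
  set.seed(10)
  emb <- rbind(matrix(rnorm(60, sd = 0.1), ncol = 2),
               matrix(rnorm(60, sd = 0.1) + 5, ncol = 2))
  traces <- matrix(rnorm(60 * 7), 60, 7)
  cl <- cluster_kmeans(emb, traces, k = 2, seed = 4)
  for (g in 1:2) {
    expect_equal(cl$centers_ts[g, ],
                 colMeans(traces[cl$labels == g, , drop = FALSE]))
  }
  expect_equal(cl$auc, rowSums(cl$centers_ts))
})

test_that("chamber selection ranks by accumulated fluorescence with id ties", {
  fake <- structure(list(auc = c(5, 50, 40), k = 3L), class = "clustering_result")
  expect_equal(select_chamber_clusters(fake), c(2L, 3L))
  fake$auc <- c(10, 10, 3)
  expect_equal(select_chamber_clusters(fake), c(1L, 2L))
})

test_that("NCC identities and hand-computed value hold exactly", {
  a <- c(1, 2, 3, 4)
  b <- c(1, -1, -1, 1)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -a), -1)
  # four-term sum (-1.5, 0.5, -0.5, 1.5 products) cancels exactly
  expect_equal(ncc(a, b), 0)
  expect_error(ncc(a, rep(2, 4)), "zero-variance")
  expect_error(ncc(a, c(1, 2)), "length")
})

test_that("NCC matches Pearson correlation and is affine invariant", {
  set.seed(21)
  for (i in 1:50) {
    t_n <- sample(3:40, 1)
    a <- rnorm(t_n); b <- rnorm(t_n)
    expect_equal(ncc(a, b), stats::cor(a, b), tolerance = 1e-12)
    expect_equal(ncc(a, b), ncc(b, a))
    alpha <- stats::runif(1, 0.1, 5); beta <- rnorm(1)
    expect_equal(ncc(alpha * a + beta, b), ncc(a, b), tolerance = 1e-12)
    expect_equal(ncc(-alpha * a + beta, b), -ncc(a, b), tolerance = 1e-12)
  }
})

test_that("NCC maps compose per-pixel correlations with bounds", {
  t_n <- 30
  c1 <- sin(seq(0, 2 * pi, length.out = t_n)) + 2
  c2 <- seq(1, 4, length.out = t_n)
  h <- 8L; w <- 8L
  frames <- array(1, c(h, w, 1L, t_n))
  frames[1, 1, 1, ] <- 5 * c1 + 3     # pure center-1 pixel
  frames[2, 5, 1, ] <- c2             # pure center-2 pixel
  frames[4, 4, 1, ] <- rep(2, t_n)    # zero-variance pixel
  v <- video_stack(frames, 10, bit_depth = 8L)
  mask <- matrix(0L, h, w); mask[1, 1] <- 1L; mask[2, 5] <- 1L; mask[4, 4] <- 1L
  px <- extract_timeseries(v, mask)
  maps <- ncc_maps(px, rbind(c1, c2), c(h, w))

  expect_equal(maps$ncc_c1[1, 1], 1)
  expect_equal(maps$ncc_c2[2, 5], 1)
  expect_equal(maps$ncc_diff[1, 1], 1 - ncc(c1, c2))
  expect_true(is.na(maps$ncc_c1[4, 4]) && is.na(maps$ncc_diff[4, 4]))
  expect_true(is.na(maps$ncc_c1[8, 8]))  # background stays undefined
  defined <- !is.na(maps$ncc_diff)
  expect_true(all(abs(maps$ncc_c1[defined]) <= 1))
  expect_true(all(abs(maps$ncc_diff[defined]) <= 2))

  # identical centers cancel everywhere defined
  maps_same <- ncc_maps(px, rbind(c1, c1), c(h, w))
  expect_true(all(maps_same$ncc_diff[!is.na(maps_same$ncc_diff)] == 0))

  expect_error(ncc_maps(px, rbind(rep(1, t_n), c2), c(h, w)), "zero variance")
})

test_that("margination partitions the foreground disjointly", {
  t_n <- 20
  c1 <- exp(-seq(0, 3, length.out = t_n))
  c2 <- seq(0, 2, length.out = t_n)
  set.seed(31)
  h <- 10L; w <- 10L
  frames <- array(0, c(h, w, 1L, t_n))
  for (r in 1:h) for (c in 1:w) {
    mix <- stats::runif(1)
    frames[r, c, 1, ] <- 10 + 40 * (mix * c1 + (1 - mix) * c2)
  }
  v <- video_stack(frames, 10)
  px <- extract_timeseries(v, matrix(1L, h, w))
  maps <- ncc_maps(px, rbind(c1, c2), c(h, w))

  res0 <- marginate(maps, epsilon = 0)
  total <- res0$chamber1_mask + res0$chamber2_mask + res0$boundary_mask
  expect_true(all(total[maps$foreground == 1] == 1))  # exact partition
  expect_true(all(total[maps$foreground == 0] == 0))

  res2 <- marginate(maps, epsilon = 2)
  expect_equal(sum(res2$chamber1_mask) + sum(res2$chamber2_mask), 0)
  expect_equal(res2$boundary_mask, maps$foreground, ignore_attr = TRUE)

  res <- marginate(maps, epsilon = 0.05)
  expect_true(all(res$chamber1_mask + res$chamber2_mask +
                    res$boundary_mask <= 1))
})

test_that("largest-component filter keeps one connected region", {
  m <- matrix(0L, 10, 10)
  m[2:3, 2:3] <- 1L       # 4 pixels
  m[7:9, 6:9] <- 1L       # 12 pixels
  m[1, 10] <- 1L          # isolated pixel
  filtered <- fluormargin:::largest_component(m)
  expect_equal(sum(filtered), 12L)
  expect_true(all(filtered[7:9, 6:9] == 1L))
})
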