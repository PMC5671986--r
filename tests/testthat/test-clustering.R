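test_that("K-means handles degenerate geometries exactly", {
  set.seed(51)
  # N = k distinct points: zero objective, centroids permute the points
  X <- matrix(rnorm(4 * 6), 4L, 6L)
  fit <- clusterKMeans(X, clusterConfig(k = 4L, replicates = 3L, seed = 1L))
  expect_lt(objectiveValue(fit), 1e-12)
  perm <- apply(sqDistMatrixForTest(clusterCentroids(fit), X), 1L, which.min)
  expect_identical(sort(perm), 1:4)
  expect_equal(clusterCentroids(fit)[order(perm), ], X[sort(perm), ],
               tolerance = 1e-12)

  # all points identical: objective 0 for any k
  same <- matrix(1, 5L, 3L)
  fit2 <- clusterKMeans(same, clusterConfig(k = 2L, replicates = 2L,
                                            seed = 1L))
  expect_identical(objectiveValue(fit2), 0)

  expect_error(clusterKMeans(X, clusterConfig(k = 10L)), "fewer points")
})

test_that("K-means on separated clouds matches the exhaustive-partition oracle", {
  cl <- makeClouds(6L, rbind(c(0, 0, 0), c(10, 10, 10)), spread = 0.5,
                   seed = 52L)
  fit <- clusterKMeans(cl$X, clusterConfig(k = 2L, replicates = 5L,
                                           seed = 2L))
  # oracle: enumerate all 2^12 assignments, minimizing J
  n <- nrow(cl$X)
  bestJ <- Inf
  bestAssign <- NULL
  for (code in 0:(2^n - 1)) {
    assign <- as.integer(intToBits(code)[1:n]) + 1L
    if (length(unique(assign)) < 2L) next
    J <- 0
    for (g in 1:2) {
      pts <- cl$X[assign == g, , drop = FALSE]
      J <- J + sum(sweep(pts, 2L, colMeans(pts))^2)
    }
    if (J < bestJ) { bestJ <- J; bestAssign <- assign }
  }
  expect_equal(objectiveValue(fit), bestJ, tolerance = 1e-9)
  agree <- mean(hardLabels(fit) == bestAssign)
  expect_true(agree %in% c(0, 1))        # identical up to label swap
  # each centroid is exactly the mean of its optimal cluster
  for (g in unique(hardLabels(fit))) {
    expect_equal(clusterCentroids(fit)[g, ],
                 colMeans(cl$X[hardLabels(fit) == g, , drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("K-means agrees with stats::kmeans on easy data", {
  cl <- makeClouds(20L, rbind(c(0, 0), c(8, 0), c(0, 8)), spread = 0.5,
                   seed = 53L)
  ours <- clusterKMeans(cl$X, clusterConfig(k = 3L, replicates = 10L,
                                            seed = 3L))
  ref <- kmeans(cl$X, centers = 3L, nstart = 20L, iter.max = 100L)
  expect_equal(objectiveValue(ours), ref$tot.withinss, tolerance = 1e-6)
})

test_that("FCM memberships are a proper fuzzy partition", {
  cl <- makeClouds(15L, rbind(c(0, 0), c(6, 6), c(-6, 6)), spread = 0.8,
                   seed = 54L)
  fit <- clusterFCM(cl$X, clusterConfig(k = 3L, m = 2, replicates = 4L,
                                        seed = 4L))
  U <- membershipMatrix(fit)
  expect_true(all(U >= 0 & U <= 1))
  expect_lt(max(abs(rowSums(U) - 1)), 1e-9)
  expect_identical(hardLabels(fit), max.col(U, ties.method = "first"))

  # a point coinciding with a centroid takes membership 1 there
  X2 <- rbind(clusterCentroids(fit)[1L, ], cl$X)
  fit2 <- clusterFCM(X2, clusterConfig(k = 3L, m = 2, replicates = 4L,
                                       seed = 4L))
  d <- sqDistMatrixForTest(X2[1L, , drop = FALSE],
                           clusterCentroids(fit2))
  if (any(d < 1e-20)) {
    expect_equal(max(membershipMatrix(fit2)[1L, ]), 1)
  }
  expect_error(clusterFCM(cl$X, clusterConfig(k = 3L, m = 1)),
               "hard K-means")
})

test_that("FCM at m near 1 reproduces K-means labels from a shared seed", {
  cl <- makeClouds(25L, rbind(c(0, 0, 0), c(9, 0, 0), c(0, 9, 0),
                              c(0, 0, 9)), spread = 0.6, seed = 55L)
  km <- clusterKMeans(cl$X, clusterConfig(k = 4L, replicates = 5L,
                                          seed = 10L))
  fc <- clusterFCM(cl$X, clusterConfig(k = 4L, m = 1.05, replicates = 5L,
                                       seed = 10L))
  expect_identical(hardLabels(fc), hardLabels(km))
})

test_that("objective traces are non-increasing and runs are seed-reproducible", {
  cl <- makeClouds(20L, rbind(c(0, 0), c(5, 5), c(-5, 5)), spread = 1.2,
                   seed = 56L)
  km <- clusterKMeans(cl$X, clusterConfig(k = 3L, replicates = 3L,
                                          seed = 6L))
  fc <- clusterFCM(cl$X, clusterConfig(k = 3L, m = 2, replicates = 3L,
                                       seed = 6L))
  expect_true(all(diff(objectiveTrace(km)) <= 1e-9))
  expect_true(all(diff(objectiveTrace(fc)) <= 1e-9))
  expect_equal(objectiveValue(km), min(km@replicateObjectives))
  expect_equal(objectiveValue(fc), min(fc@replicateObjectives))

  km2 <- clusterKMeans(cl$X, clusterConfig(k = 3L, replicates = 3L,
                                           seed = 6L))
  fc2 <- clusterFCM(cl$X, clusterConfig(k = 3L, m = 2, replicates = 3L,
                                        seed = 6L))
  expect_identical(clusterCentroids(km2), clusterCentroids(km))
  expect_identical(hardLabels(km2), hardLabels(km))
  expect_identical(membershipMatrix(fc2), membershipMatrix(fc))
})

test_that("FCM matches e1071::cmeans quality on well-separated data", {
  skip_if_not_installed("e1071")
  cl <- makeClouds(20L, rbind(c(0, 0), c(7, 7)), spread = 0.7, seed = 57L)
  ours <- clusterFCM(cl$X, clusterConfig(k = 2L, m = 2, replicates = 5L,
                                         seed = 7L))
  set.seed(7)
  ref <- e1071::cmeans(cl$X, centers = 2L, m = 2, iter.max = 500L)
  # same fuzzy objective at the optimum (both converge on this geometry)
  refJ <- sum(ref$membership^2 *
                sqDistMatrixForTest(cl$X, ref$centers))
  expect_equal(objectiveValue(ours), refJ, tolerance = 1e-3)
  # hard partitions agree up to label permutation
  tab <- table(hardLabels(ours), ref$cluster)
  expect_identical(unname(sort(apply(tab, 1L, max))),
                   unname(sort(as.integer(table(cl$truth)))))
})

test_that("elbow curve has its closed forms at the extremes and a knee at k_true", {
  cl <- makeClouds(12L, 6 * diag(4L), spread = 0.3, seed = 58L)
  # k = 1: total squared distance to the grand centroid
  e1 <- elbowCurve(cl$X, 1L, clusterConfig(replicates = 2L, seed = 8L))
  expect_equal(e1$objective,
               sum(sweep(cl$X, 2L, colMeans(cl$X))^2), tolerance = 1e-9)
  # k = N: zero
  eN <- elbowCurve(cl$X, nrow(cl$X),
                   clusterConfig(replicates = 2L, seed = 8L))
  expect_lt(eN$objective, 1e-9)

  curve <- elbowCurve(cl$X, 1:6, clusterConfig(replicates = 5L, seed = 8L))
  expect_true(all(diff(curve$objective) <= 1e-9))
  drops <- -diff(curve$objective) / curve$objective[-nrow(curve)]
  expect_lte(which.max(drops) + 1L, 4L)   # knee reached by k_true = 4
  expect_error(elbowCurve(cl$X, integer(0)), "empty")
})

test_that("silhouette matches the brute-force oracle exactly", {
  set.seed(59)
  for (k in 2:4) {
    X <- matrix(rnorm(50 * 3), 50L)
    labels <- sample.int(k, 50L, replace = TRUE)
    labels[seq_len(k)] <- seq_len(k)     # every cluster non-empty
    res <- silhouetteWidths(X, labels)
    oracle <- silhouetteOracle(X, labels)
    expect_equal(res$a, oracle$a, tolerance = 1e-12)
    expect_equal(res$b, oracle$b, tolerance = 1e-12)
    expect_equal(res$s, oracle$s, tolerance = 1e-12)
  }
})

test_that("silhouette trivial cases and the cluster-package cross-check", {
  # two coincident pairs far apart: s = 1 everywhere
  X <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  res <- silhouetteWidths(X, c(1L, 1L, 2L, 2L))
  expect_equal(res$s, rep(1, 4L))
  # a point with a == b scores 0
  X2 <- rbind(c(0, 0), c(2, 0), c(1, 0), c(3, 0))
  res2 <- silhouetteWidths(X2, c(1L, 1L, 2L, 2L))
  expect_equal(res2$s[1L], (res2$b[1L] - res2$a[1L]) /
                 max(res2$a[1L], res2$b[1L]))
  expect_error(silhouetteWidths(X, rep(1L, 4L)), "at least 2")

  skip_if_not_installed("cluster")
  set.seed(60)
  X3 <- matrix(rnorm(40 * 4), 40L)
  lab <- rep(1:4, each = 10L)
  ours <- silhouetteWidths(X3, lab)
  ref <- cluster::silhouette(lab, dist(X3))
  expect_equal(ours$s, as.numeric(ref[, "sil_width"]), tolerance = 1e-12)
})
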