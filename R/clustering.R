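# Hard K-means and fuzzy C-means over peak topographies, with kmeans++
# initialization, replicates, objective tracking, and cluster-validity
# diagnostics (elbow curve, silhouette).

#' Clustering configuration
#'
#' @param k number of clusters (>= 1). k = 5 is the operating default: on
#'   EEG peak maps, one pair of the five resulting centroids typically
#'   proves a polarity inversion and is merged afterwards, leaving the
#'   four classical microstate templates (see
#'   [mergePolarityDuplicates()]).
#' @param m fuzzy C-means fuzzifier (> 1; ignored by hard K-means). m = 2
#'   is the conventional default; m near 1 approaches hard assignments.
#' @param replicates number of random restarts; the run with the lowest
#'   final objective wins (ties: lowest replicate index).
#' @param maxIter iteration cap; if `NULL`, 5000 for K-means and 1000 for
#'   FCM.
#' @param tol convergence tolerance: absolute change of the objective
#'   (K-means) or max absolute change of the membership matrix (FCM).
#' @param seed integer seed making the whole run reproducible, or `NULL`.
#' @return a list of class `clusterConfig`.
#' @export
clusterConfig <- function(k = 5L, m = 2, replicates = 10L, maxIter = NULL,
                          tol = 1e-6, seed = NULL) {
  stopifnot(k >= 1L, m >= 1, replicates >= 1L, tol > 0)
  structure(list(k = as.integer(k), m = m, replicates = as.integer(replicates),
                 maxIter = maxIter, tol = tol, seed = seed),
            class = "clusterConfig")
}

# kmeans++ seeding: first centroid uniform, then points with probability
# proportional to squared distance to the nearest chosen centroid.
kmeansppInit <- function(X, k) {
  N <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(N, 1L)
  centers[1L, ] <- X[idx, ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      idx <- sample.int(N, 1L)
    } else {
      idx <- sample.int(N, 1L, prob = d2 / sum(d2))
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

.lloyd <- function(X, centers, maxIter, tol) {
  N <- nrow(X); k <- nrow(centers)
  labels <- integer(N)
  trace <- numeric(0L)
  Jprev <- Inf
  for (iter in seq_len(maxIter)) {
    D2 <- sqDistMatrix(X, centers)
    newLabels <- max.col(-D2, ties.method = "first")
    # empty-cluster repair: reseed the empty centroid to the point
    # farthest from its assigned centroid and move that point into it
    repeat {
      counts <- tabulate(newLabels, nbins = k)
      empty <- which(counts == 0L)
      if (!length(empty)) break
      dAssigned <- D2[cbind(seq_len(N), newLabels)]
      eligible <- counts[newLabels] > 1L   # never empty another cluster
      if (!any(eligible)) break
      far <- which.max(replace(dAssigned, !eligible, -Inf))
      centers[empty[1L], ] <- X[far, ]
      newLabels[far] <- empty[1L]
      D2[, empty[1L]] <- rowSums(sweep(X, 2L, centers[empty[1L], ])^2)
    }
    J <- sum(D2[cbind(seq_len(N), newLabels)])
    trace <- c(trace, J)
    converged <- identical(newLabels, labels) || abs(Jprev - J) < tol
    labels <- newLabels
    Jprev <- J
    # centroid update
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    }
    if (converged) break
  }
  # final objective with updated centroids (never larger than the last
  # recorded assignment objective)
  D2 <- sqDistMatrix(X, centers)
  J <- sum(D2[cbind(seq_len(N), labels)])
  trace[length(trace)] <- J
  list(centers = centers, labels = labels, objective = J, trace = trace)
}

#' Hard K-means clustering of peak maps
#'
#' Lloyd iterations from kmeans++ initialization with Euclidean distance,
#' minimizing the within-cluster sum of squared distances
#' \deqn{J(X, k) = \sum_{i=1}^{N} \sum_{j=1}^{k} \|x_i - c_j\|^2}
#' (each point contributing its assigned centroid's term). Runs
#' `replicates` restarts and returns the one with the lowest final J.
#' Empty clusters are repaired by reseeding the empty centroid to the
#' point farthest from its current centroid.
#'
#' @param maps N x C matrix of z-normalized peak maps
#'   (from [extractPeakMaps()]).
#' @param cfg a [clusterConfig()]. `m` is ignored.
#' @return a [ClusterResult-class]; `U` is the one-hot encoding of the
#'   hard labels.
#' @export
clusterKMeans <- function(maps, cfg = clusterConfig()) {
  X <- as.matrix(maps)
  N <- nrow(X); k <- cfg$k
  if (k < 1L) stop("k must be >= 1")
  if (N < k) stop("fewer points (", N, ") than clusters (", k, ")")
  if (any(!is.finite(X))) stop("maps must be finite")
  maxIter <- if (is.null(cfg$maxIter)) 5000L else cfg$maxIter

  seeds <- childSeeds(cfg$seed, cfg$replicates)
  best <- NULL
  repObj <- numeric(cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    fit <- withSeed(seeds[[r]], {
      init <- kmeansppInit(X, k)
      .lloyd(X, init, maxIter, cfg$tol)
    })
    repObj[r] <- fit$objective
    if (is.null(best) || fit$objective < best$objective - 0) {
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  }
  U <- matrix(0, N, k)
  U[cbind(seq_len(N), best$labels)] <- 1
  new("ClusterResult", centroids = best$centers, hardLabels = best$labels,
      U = U, objective = best$objective, objectiveTrace = best$trace,
      replicateObjectives = repObj, method = "kmeans",
      config = unclass(cfg))
}

.fcmMembership <- function(D2, m, zeroTol = 1e-12) {
  N <- nrow(D2); k <- ncol(D2)
  U <- matrix(0, N, k)
  zero <- D2 <= zeroTol
  anyZero <- rowSums(zero) > 0L
  if (any(anyZero)) {
    # coincident with one or more centroids: split membership equally
    zr <- zero[anyZero, , drop = FALSE]
    U[anyZero, ] <- zr / rowSums(zr)
  }
  if (any(!anyZero)) {
    Ds <- D2[!anyZero, , drop = FALSE]
    # normalize by the row minimum for numerical stability at small m - 1
    W <- (Ds / apply(Ds, 1L, min))^(-1 / (m - 1))
    U[!anyZero, ] <- W / rowSums(W)
  }
  U
}

.fcmFit <- function(X, centers, m, maxIter, tol) {
  N <- nrow(X); k <- nrow(centers)
  trace <- numeric(0L)
  Uprev <- matrix(0, N, k)
  for (iter in seq_len(maxIter)) {
    D2 <- sqDistMatrix(X, centers)
    U <- .fcmMembership(D2, m)
    Um <- U^m
    centers <- crossprod(Um, X) / colSums(Um)
    D2 <- sqDistMatrix(X, centers)
    trace <- c(trace, sum(Um * D2))
    if (max(abs(U - Uprev)) < tol) {
      Uprev <- U
      break
    }
    Uprev <- U
  }
  list(centers = centers, U = Uprev, objective = trace[length(trace)],
       trace = trace)
}

#' Fuzzy C-means clustering of peak maps
#'
#' Alternating minimization of the fuzzy objective
#' \deqn{J(X, m, k) = \sum_{i=1}^{N} \sum_{j=1}^{k} U_{ij}^m \|x_i - c_j\|^2}
#' with the standard update pair
#' \deqn{U_{ij} = \Big[\sum_l (\|x_i-c_j\| / \|x_i-c_l\|)^{2/(m-1)}\Big]^{-1},
#'       \quad c_j = \sum_i U_{ij}^m x_i \big/ \sum_i U_{ij}^m.}
#' Initialization is kmeans++ (shared with [clusterKMeans()]: the same
#' seed yields the same initial centroids). A point coinciding with one or
#' more centroids splits membership 1 equally among the coinciding
#' centroids. Convergence when the max absolute change in U falls below
#' `tol`; the best of `replicates` restarts by final J is returned.
#'
#' @param maps N x C matrix of z-normalized peak maps.
#' @param cfg a [clusterConfig()]; requires `m > 1` (for m = 1 the limit
#'   is hard K-means — use [clusterKMeans()]).
#' @return a [ClusterResult-class] with the full membership matrix `U`;
#'   `hardLabels` is the row-wise argmax of U.
#' @export
clusterFCM <- function(maps, cfg = clusterConfig()) {
  X <- as.matrix(maps)
  N <- nrow(X); k <- cfg$k
  if (cfg$m <= 1) {
    stop("fuzzifier m must be > 1; for m = 1 the algorithm reduces to ",
         "hard K-means - use clusterKMeans()")
  }
  if (k < 1L) stop("k must be >= 1")
  if (N < k) stop("fewer points (", N, ") than clusters (", k, ")")
  if (any(!is.finite(X))) stop("maps must be finite")
  maxIter <- if (is.null(cfg$maxIter)) 1000L else cfg$maxIter

  seeds <- childSeeds(cfg$seed, cfg$replicates)
  best <- NULL
  repObj <- numeric(cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    fit <- withSeed(seeds[[r]], {
      init <- kmeansppInit(X, k)
      .fcmFit(X, init, cfg$m, maxIter, cfg$tol)
    })
    repObj[r] <- fit$objective
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  labels <- max.col(best$U, ties.method = "first")
  new("ClusterResult", centroids = best$centers, hardLabels = labels,
      U = best$U, objective = best$objective, objectiveTrace = best$trace,
      replicateObjectives = repObj, method = "fcm", config = unclass(cfg))
}

#' Within-cluster total distance for increasing k (elbow curve)
#'
#' Runs [clusterKMeans()] (or [clusterFCM()]) for each k in `kRange` and
#' records the best-of-replicates final objective: the total distance of
#' the points to their assigned cluster centroids, used to locate the
#' "knee" when choosing the number of template maps.
#'
#' @param maps N x C peak-map matrix.
#' @param kRange integer vector of cluster counts to evaluate.
#' @param cfg base [clusterConfig()] (its `k` is overridden).
#' @param method `"kmeans"` (default) or `"fcm"`.
#' @return data.frame with columns `k` and `objective`.
#' @export
elbowCurve <- function(maps, kRange, cfg = clusterConfig(),
                       method = c("kmeans", "fcm")) {
  method <- match.arg(method)
  kRange <- as.integer(kRange)
  if (!length(kRange)) stop("empty kRange")
  if (any(kRange < 1L) || any(kRange > nrow(maps))) {
    stop("kRange must lie within [1, N]")
  }
  obj <- vapply(kRange, function(k) {
    cfg$k <- k
    fit <- if (method == "kmeans") clusterKMeans(maps, cfg)
           else clusterFCM(maps, cfg)
    fit@objective
  }, numeric(1L))
  data.frame(k = kRange, objective = obj)
}

#' Silhouette widths of a hard clustering
#'
#' For each point i, with a_i the mean distance to the other members of
#' its own cluster and b_i the minimum over other clusters of the mean
#' distance to that cluster's members,
#' \deqn{S_i = (b_i - a_i) / \max(a_i, b_i) \in [-1, 1].}
#' Values toward 1 indicate a point well matched to its cluster; 0 that it
#' could equally belong elsewhere; negative values a bad match. Points in
#' singleton clusters get S_i = 0. Euclidean distance, exact evaluation.
#'
#' @param maps N x C matrix.
#' @param labels integer cluster labels (at least 2 non-empty clusters).
#' @return data.frame with columns `label`, `a`, `b`, `s`.
#' @export
silhouetteWidths <- function(maps, labels) {
  X <- as.matrix(maps)
  labels <- as.integer(labels)
  N <- nrow(X)
  stopifnot(length(labels) == N)
  used <- sort(unique(labels))
  if (length(used) < 2L) stop("silhouette requires at least 2 clusters")
  D <- as.matrix(stats::dist(X))
  counts <- table(factor(labels, levels = used))
  # mean distance from every point to every cluster
  M <- sapply(used, function(g) {
    rowSums(D[, labels == g, drop = FALSE])
  })
  a <- numeric(N); b <- numeric(N); s <- numeric(N)
  for (i in seq_len(N)) {
    gi <- match(labels[i], used)
    ni <- counts[gi]
    if (ni > 1L) {
      a[i] <- M[i, gi] / (ni - 1L)    # exclude the point itself
    } else {
      a[i] <- 0
    }
    b[i] <- min(M[i, -gi] / as.numeric(counts[-gi]))
    s[i] <- if (ni == 1L) 0 else (b[i] - a[i]) / max(a[i], b[i])
    if (is.nan(s[i])) s[i] <- 0       # a_i = b_i = 0 (coincident clusters)
  }
  data.frame(label = labels, a = a, b = b, s = s)
}
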