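makeResult <- function(centroids, labels, method = "kmeans") {
  k <- nrow(centroids); N <- length(labels)
  U <- matrix(0, N, k)
  U[cbind(seq_len(N), labels)] <- 1
  new("ClusterResult", centroids = centroids, hardLabels = labels, U = U,
      objective = 1, objectiveTrace = 1, replicateObjectives = 1,
      method = method, config = list())
}

test_that("a perfectly inverted template pair is merged and relabeled", {
  set.seed(71)
  t1 <- as.numeric(zNormalizeRows(matrix(rnorm(16), 1L)))
  out <- mergePolarityDuplicates(makeResult(rbind(t1, -t1),
                                            rep(c(1L, 2L), 5L)))
  expect_identical(nStates(out$templates), 1L)
  expect_identical(hardLabels(out$result), rep(1L, 10L))
  log <- mergeLog(out$templates)
  expect_identical(nrow(log), 1L)
  expect_lt(log$correlation, -0.999)
})

test_that("near-orthogonal templates are left untouched (and merge is idempotent)", {
  tm <- generateTemplates(32L, 4L, seed = 72L)
  res <- makeResult(tm, rep(1:4, 6L))
  out <- mergePolarityDuplicates(res)
  expect_identical(nStates(out$templates), 4L)
  expect_identical(nrow(mergeLog(out$templates)), 0L)
  again <- mergePolarityDuplicates(out$result)
  expect_identical(nStates(again$templates), 4L)
  expect_equal(templateMaps(again$templates), templateMaps(out$templates))
  expect_error(mergePolarityDuplicates(res, threshold = 0), "\\(0, 1\\]")
  expect_error(mergePolarityDuplicates(res, threshold = 1.2), "\\(0, 1\\]")
})

test_that("a k=5 clustering of 4-template data merges exactly the inverted pair", {
  tm <- generateTemplates(32L, 4L, seed = 73L)
  # modes: both polarities of template 1, plus templates 2..4
  set.seed(73)
  modes <- rbind(tm[1L, ], -tm[1L, ], tm[2L, ], tm[3L, ], tm[4L, ])
  idx <- sample.int(5L, 400L, replace = TRUE)
  X <- modes[idx, ] + matrix(rnorm(400L * 32L, sd = 0.2), 400L)
  km <- clusterKMeans(zNormalizeRows(X),
                      clusterConfig(k = 5L, replicates = 5L, seed = 9L))
  out <- mergePolarityDuplicates(km)
  expect_identical(nStates(out$templates), 4L)
  expect_identical(nrow(mergeLog(out$templates)), 1L)
  expect_lt(mergeLog(out$templates)$correlation, -0.95)
  # membership columns of the merged pair were summed: rows still sum to 1
  expect_lt(max(abs(rowSums(membershipMatrix(out$result)) - 1)), 1e-9)
})

test_that("template correlation recovers identity, permutation and sign structure", {
  A <- TemplateSet(generateTemplates(24L, 4L, seed = 74L))
  expect_equal(diag(correlateTemplates(A, A)), rep(1, 4L))

  perm <- c(3L, 1L, 4L, 2L)
  signs <- c(1, -1, 1, -1)
  B <- TemplateSet(templateMaps(A)[perm, ] * signs)
  R <- correlateTemplates(A, B, polarityInvariant = TRUE)
  expect_equal(R[cbind(perm, 1:4)], rep(1, 4L), tolerance = 1e-12)
  expect_identical(attr(R, "sign")[cbind(perm, 1:4)], signs)

  # element-wise against the direct formula
  set.seed(74)
  C <- TemplateSet(templateMaps(A) + matrix(rnorm(96, sd = 0.4), 4L))
  R2 <- correlateTemplates(A, C)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(R2[i, j], cor(templateMaps(A)[i, ], templateMaps(C)[j, ]),
                 tolerance = 1e-12)
  }
  D <- TemplateSet(matrix(rnorm(10), 2L))
  expect_error(correlateTemplates(A, D), "channel")
})

test_that("label alignment equals exhaustive search and undoes a known permutation", {
  A <- TemplateSet(generateTemplates(24L, 4L, seed = 75L))
  expect_identical(alignTemplates(A, A)$perm, 1:4)

  perm <- c(2L, 4L, 1L, 3L)
  set.seed(75)
  noisy <- templateMaps(A)[perm, ] * c(-1, 1, -1, 1) +
    matrix(rnorm(96, sd = 0.3), 4L)
  B <- TemplateSet(noisy)
  alg <- alignTemplates(A, B)
  # alg$perm[j] is B's map matching A's map j: inverse of perm
  expect_identical(alg$perm[perm], 1:4)

  # exhaustive oracle over all 24 permutations
  R <- abs(correlateTemplates(A, B))
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == 4L), ]
  scores <- apply(perms, 1L, function(p) sum(R[cbind(1:4, as.integer(p))]))
  expect_equal(alg$total, max(scores), tolerance = 1e-12)

  expect_error(alignTemplates(A, TemplateSet(generateTemplates(24L, 3L,
                                                               seed = 1L))),
               "different k")
})

test_that("applying an alignment relabels maps, labels and memberships consistently", {
  A <- TemplateSet(generateTemplates(24L, 3L, seed = 76L))
  perm <- c(3L, 1L, 2L)
  B <- TemplateSet(templateMaps(A)[perm, ])
  res <- makeResult(templateMaps(A)[perm, ], rep(1:3, 4L))
  alg <- alignTemplates(A, B)
  ap <- applyAlignment(B, alg, res)
  expect_equal(templateMaps(ap$templates), templateMaps(A),
               tolerance = 1e-9, ignore_attr = TRUE)
  # a point labeled j in B must now carry A's label for the same map
  R <- correlateTemplates(A, TemplateSet(clusterCentroids(res)))
  for (i in seq_along(hardLabels(res))) {
    oldLbl <- hardLabels(res)[i]
    expect_identical(hardLabels(ap$result)[i],
                     which.max(R[, oldLbl]))
  }
})

test_that("backfitting is polarity- and scale-invariant and exact on pure maps", {
  tm <- generateTemplates(24L, 4L, seed = 77L)
  tset <- TemplateSet(tm)
  X <- t(rbind(3 * tm[2L, ], -tm[3L, ], 0.5 * tm[1L, ]))
  rec <- EEGRecording(X, sfreq = 100)
  bf <- backfitTemplates(rec, tset)
  expect_identical(bf$label, c(2L, 3L, 1L))
  expect_equal(bf$abscor, rep(1, 3L), tolerance = 1e-9)

  sim <- generateRecording(synthConfig(nChannels = 24L, duration = 5,
                                       noiseSD = 0.05, seed = 78L))
  r <- rereferenceAverage(sim$recording)
  bf1 <- backfitTemplates(r, TemplateSet(templateMaps(sim$truth)))
  flipped <- EEGRecording(-2.5 * eegData(r), sfreq = samplingRate(r))
  bf2 <- backfitTemplates(flipped, TemplateSet(templateMaps(sim$truth)))
  expect_identical(bf1$label, bf2$label)

  ok <- !is.na(bf1$label)
  acc <- mean(bf1$label[ok] == stateSequence(sim$truth)[ok])
  expect_gte(acc, 0.95)
})

test_that("zero-variance timepoints are left unlabeled by backfitting", {
  tm <- generateTemplates(16L, 2L, seed = 79L)
  X <- t(rbind(tm[1L, ], rep(0, 16L), tm[2L, ]))
  bf <- backfitTemplates(EEGRecording(X, sfreq = 10), TemplateSet(tm))
  expect_identical(bf$label, c(1L, NA_integer_, 2L))
})
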