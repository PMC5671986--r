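test_that("training on separable classes reaches high held-out accuracy", {
  d <- makeSeparable(n = 400L, C = 10L, k = 3L, sep = 5, noise = 0.5,
                     seed = 81L)
  model <- trainMLP(d$X, d$y, mlpConfig(seed = 81L))
  ev <- evaluateMLP(model, d$X, d$y)
  expect_gte(ev$test$accuracy, 0.98)
  # training made progress: final train loss below the first epoch's
  rep <- model@trainingReport
  expect_lt(rep$trainLoss[rep$chosenEpoch], rep$trainLoss[1L])
  # confusion rows sum to the per-class counts of the split
  counts <- table(factor(d$y[rep$splits$test], levels = 1:3))
  expect_identical(rowSums(ev$test$confusion), as.numeric(counts),
                   ignore_attr = TRUE)
})

test_that("training is seed-reproducible end to end", {
  d <- makeSeparable(n = 200L, C = 8L, k = 2L, seed = 82L)
  m1 <- trainMLP(d$X, d$y, mlpConfig(seed = 7L, maxEpochs = 200L))
  m2 <- trainMLP(d$X, d$y, mlpConfig(seed = 7L, maxEpochs = 200L))
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@W2, m2@W2)
  expect_identical(m1@trainingReport$splits, m2@trainingReport$splits)
  expect_identical(m1@trainingReport$valLoss, m2@trainingReport$valLoss)
})

test_that("the gradient-descent fallback optimizer also converges", {
  d <- makeSeparable(n = 300L, C = 8L, k = 3L, seed = 83L)
  model <- trainMLP(d$X, d$y, mlpConfig(seed = 83L, optimizer = "gdls",
                                        maxEpochs = 500L))
  expect_gte(evaluateMLP(model, d$X, d$y)$test$accuracy, 0.95)
})

test_that("prediction emits probability rows summing to 1 with the tie rule", {
  d <- makeSeparable(n = 200L, C = 6L, k = 3L, seed = 84L)
  model <- trainMLP(d$X, d$y, mlpConfig(seed = 84L))
  rec <- tinyRecording(nch = 6L, nt = 40L, seed = 84L)
  seq <- predictStateProbabilities(model, rec)
  P <- stateProbs(seq)
  expect_true(all(P >= 0 & P <= 1))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_identical(mleLabels(seq), max.col(P, ties.method = "first"))
  expect_equal(mleProbs(seq), P[cbind(1:40, mleLabels(seq))])

  # exact ties resolve to the lowest state id
  tied <- microstates:::.StateSequence(
    rbind(c(0.25, 0.25, 0.25, 0.25), c(0.1, 0.45, 0.45, 0)))
  expect_identical(mleLabels(tied), c(1L, 2L))

  wrong <- tinyRecording(nch = 5L, nt = 10L)
  expect_error(predictStateProbabilities(model, wrong), "channel count")
})

test_that("zero-variance timepoints get the uniform fallback", {
  d <- makeSeparable(n = 200L, C = 6L, k = 2L, seed = 85L)
  model <- trainMLP(d$X, d$y, mlpConfig(seed = 85L))
  X <- matrix(rnorm(6 * 5), 6L, 5L)
  X[, 3L] <- 2                       # flat topography
  expect_warning(seq <- predictStateProbabilities(
    model, EEGRecording(X, sfreq = 10)), "uniform")
  expect_equal(stateProbs(seq)[3L, ], rep(0.5, 2L))
  expect_false(labeledMask(seq)[3L])
  expect_true(is.na(mleLabels(seq)[3L]))
})

test_that("ROC/AUC behave on perfect and permuted labels, matching pROC", {
  d <- makeSeparable(n = 600L, C = 8L, k = 3L, sep = 8, noise = 0.3,
                     seed = 86L)
  model <- trainMLP(d$X, d$y, mlpConfig(seed = 86L))
  ev <- evaluateMLP(model, d$X, d$y)
  expect_equal(unname(ev$test$auc), rep(1, 3L), tolerance = 1e-9)

  # permuted labels: no signal left, AUC near chance
  set.seed(86)
  shuffled <- sample(d$y)
  evs <- evaluateMLP(model, d$X, shuffled)
  expect_true(all(abs(evs$train$auc - 0.5) < 0.05))

  skip_if_not_installed("pROC")
  P <- microstates:::.mlpForward(d$X, model@W1, model@b1, model@W2,
                                 model@b2)$P
  idx <- model@trainingReport$splits$train
  refAuc <- suppressMessages(as.numeric(
    pROC::auc(pROC::roc(shuffled[idx] == 1, P[idx, 1L], quiet = TRUE,
                        direction = "<"))))
  expect_equal(unname(evs$train$auc[1L]), refAuc, tolerance = 1e-9)
})

test_that("training rejects too-small or class-deficient inputs", {
  d <- makeSeparable(n = 20L, C = 4L, k = 3L, seed = 87L)
  expect_error(trainMLP(d$X, d$y, mlpConfig(seed = 1L)), "at least 10")
  # one vanishing class: uniform split will miss it
  d2 <- makeSeparable(n = 400L, C = 4L, k = 2L, seed = 88L)
  y <- d2$y
  y[y == 2L][-1L] <- 1L              # class 2 has a single example
  expect_error(trainMLP(d2$X, y, mlpConfig(seed = 8L)),
               "absent from the training split")
})

test_that("MLP labels agree with deterministic backfitting on noiseless data", {
  sim <- generateRecording(synthConfig(nChannels = 32L, duration = 8,
                                       noiseSD = 0, seed = 89L,
                                       inversionProb = c(0.5, 0, 0, 0)))
  rec <- rereferenceAverage(sim$recording)
  g <- computeGFP(rec)
  peaks <- detectGFPPeaks(g)
  maps <- suppressWarnings(extractPeakMaps(rec, peaks))
  labels <- stateSequence(sim$truth)[attr(maps, "sourceIndices")]
  model <- trainMLP(maps, labels, mlpConfig(seed = 89L))
  seq <- suppressWarnings(predictStateProbabilities(model, rec))
  bf <- backfitTemplates(rec, TemplateSet(templateMaps(sim$truth)))
  ok <- labeledMask(seq) & !is.na(bf$label)
  expect_gte(mean(mleLabels(seq)[ok] == bf$label[ok]), 0.99)
})

test_that("labeling certainty decreases monotonically with sensor noise", {
  tm <- generateTemplates(32L, 4L, seed = 90L)
  base <- synthConfig(nChannels = 32L, duration = 8, noiseSD = 0.4,
                      seed = 90L)
  sim <- generateRecording(base, templates = tm)
  rec <- rereferenceAverage(sim$recording)
  maps <- extractPeakMaps(rec, detectGFPPeaks(computeGFP(rec)))
  labels <- stateSequence(sim$truth)[attr(maps, "sourceIndices")]
  model <- trainMLP(maps, labels, mlpConfig(seed = 90L))

  meanCertainty <- vapply(c(0.2, 0.6, 1.2), function(ns) {
    cfg <- synthConfig(nChannels = 32L, duration = 6, noiseSD = ns,
                       seed = 91L)
    s <- generateRecording(cfg, templates = tm)
    sq <- suppressWarnings(
      predictStateProbabilities(model, rereferenceAverage(s$recording)))
    mean(mleProbs(sq)[labeledMask(sq)])
  }, numeric(1L))
  expect_true(all(diff(meanCertainty) < 0))
})
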