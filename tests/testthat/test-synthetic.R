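test_that("generated templates are smooth, decorrelated, normalized and reproducible", {
  tm <- generateTemplates(64L, 4L, seed = 111L)
  expect_identical(dim(tm), c(4L, 64L))
  expect_lt(max(abs(rowMeans(tm))), 1e-9)
  expect_lt(max(abs(apply(tm, 1L, sd) - 1)), 1e-9)
  R <- cor(t(tm))
  expect_lt(max(abs(R[upper.tri(R)])), 0.3)
  expect_identical(generateTemplates(64L, 4L, seed = 111L), tm)
  expect_false(identical(generateTemplates(64L, 4L, seed = 112L), tm))
  expect_error(generateTemplates(3L, 5L), "more templates")
})

test_that("recordings are pure functions of (config, seed)", {
  cfg <- synthConfig(nChannels = 16L, duration = 2, seed = 113L)
  a <- generateRecording(cfg)
  b <- generateRecording(cfg)
  expect_identical(eegData(a$recording), eegData(b$recording))
  expect_identical(stateSequence(a$truth), stateSequence(b$truth))
})

test_that("segment structure is contiguous with in-range states", {
  sim <- generateRecording(synthConfig(nChannels = 8L, duration = 5,
                                       seed = 114L))
  seg <- sim$truth@segments
  expect_identical(seg$start[1L], 1L)
  expect_identical(seg$end[nrow(seg)], length(stateSequence(sim$truth)))
  expect_true(all(seg$start[-1L] == seg$end[-nrow(seg)] + 1L))
  expect_true(all(seg$state %in% 1:4))
  expect_true(all(seg$sign %in% c(-1L, 1L)))
})

test_that("empirical mean dwell sits near the configured 100 ms", {
  sim <- generateRecording(synthConfig(nChannels = 4L, duration = 600,
                                       noiseSD = 0, seed = 115L))
  seg <- sim$truth@segments
  # drop the truncated final segment
  dwellMs <- (seg$end - seg$start + 1L)[-nrow(seg)] / 160 * 1000
  expect_lt(abs(mean(dwellMs) - 100) / 100, 0.10)
})

test_that("the noiseless limit backfits perfectly", {
  sim <- generateRecording(synthConfig(nChannels = 16L, duration = 5,
                                       noiseSD = 0, seed = 116L))
  rec <- sim$recording
  bf <- backfitTemplates(rec, TemplateSet(templateMaps(sim$truth)))
  ok <- !is.na(bf$label)
  expect_gt(mean(ok), 0.95)
  expect_equal(bf$abscor[ok], rep(1, sum(ok)), tolerance = 1e-6)
  expect_identical(bf$label[ok], stateSequence(sim$truth)[ok])
})

test_that("backfit accuracy strictly decreases with noise", {
  tm <- generateTemplates(16L, 4L, seed = 117L)
  acc <- vapply(c(0.2, 0.8, 2), function(ns) {
    sim <- generateRecording(synthConfig(nChannels = 16L, duration = 5,
                                         noiseSD = ns, seed = 118L),
                             templates = tm)
    bf <- backfitTemplates(sim$recording, TemplateSet(tm))
    ok <- !is.na(bf$label)
    mean(bf$label[ok] == stateSequence(sim$truth)[ok])
  }, numeric(1L))
  expect_true(all(diff(acc) < 0))
})

test_that("cohorts share templates, tag conditions and scale GFP with gain", {
  cohort <- generateCohort(4L, synthConfig(nChannels = 16L, duration = 2,
                                           seed = 119L))
  expect_length(cohort, 8L)
  expect_setequal(names(cohort),
                  as.vector(outer(sprintf("S%02d", 1:4),
                                  c("real", "imagined"), paste, sep = ".")))
  expect_identical(subjectCondition(cohort[["S02.imagined"]]$recording),
                   "imagined")
  expect_identical(subjectID(cohort[["S03.real"]]$recording), "S03")
  # one shared template set
  expect_identical(templateMaps(cohort[[1L]]$truth),
                   templateMaps(cohort[[7L]]$truth))

  gains <- attr(cohort, "gains")
  meanGFP <- vapply(sprintf("S%02d", 1:4), function(s) {
    mean(computeGFP(cohort[[paste0(s, ".real")]]$recording))
  }, numeric(1L))
  expect_identical(order(gains), order(meanGFP))

  again <- generateCohort(4L, synthConfig(nChannels = 16L, duration = 2,
                                          seed = 119L))
  expect_identical(eegData(again[[5L]]$recording),
                   eegData(cohort[[5L]]$recording))
  expect_error(generateCohort(2L, synthConfig(seed = 1L),
                              gainRange = c(-1, 1)), "gainRange")
})

test_that("recovery scoring is exact for self and sign-flipped templates", {
  sim <- generateRecording(synthConfig(nChannels = 16L, duration = 2,
                                       seed = 120L))
  tset <- TemplateSet(templateMaps(sim$truth))
  self <- scoreRecovery(tset, sim$truth,
                        labels = stateSequence(sim$truth))
  expect_equal(self$matches$absCor, rep(1, 4L), tolerance = 1e-12)
  expect_identical(self$matches$estimateId, 1:4)
  expect_equal(self$accuracy, 1)

  flipped <- TemplateSet(-templateMaps(sim$truth))
  sf <- scoreRecovery(flipped, sim$truth)
  expect_equal(sf$matches$absCor, rep(1, 4L), tolerance = 1e-12)

  # k mismatch: report padded with unmatched entries
  three <- TemplateSet(templateMaps(sim$truth)[1:3, ])
  pad <- scoreRecovery(three, sim$truth)
  expect_identical(sum(is.na(pad$matches$estimateId)), 1L)
})

test_that("configuration validation guards the generator", {
  expect_warning(synthConfig(meanDwell = 50), "80-120")
  expect_error(synthConfig(transitionMatrix = matrix(1, 4L, 4L)),
               "row-stochastic")
  expect_error(synthConfig(noiseSD = -1))
  bad <- synthConfig(seed = 1L)
  tm <- generateTemplates(8L, 2L, seed = 1L)
  expect_error(generateRecording(bad, templates = tm))
})
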