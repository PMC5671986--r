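# Synthetic multichannel EEG with known microstate structure.
#
# The generator emulates the features of resting-style EEG that the
# pipeline depends on: k smooth, mutually decorrelated template
# topographies; quasi-stable state segments of ~80-120 ms drawn from a
# first-order Markov chain; oscillatory amplitude modulation of the
# active template (so GFP peaks occur at carrier extrema where SNR is
# maximal); occasional polarity inversion of a segment's topography;
# additive Gaussian sensor noise; and per-subject gain differences that
# drive labeling certainty. Everything is a pure function of
# (config, seed).

#' Synthetic EEG configuration
#'
#' @param nChannels number of channels (default 64).
#' @param kTemplates number of latent templates (default 4).
#' @param sfreq sampling rate in Hz (default 160).
#' @param duration recording length in seconds.
#' @param meanDwell mean microstate dwell time in ms (default 100; values
#'   outside the 80-120 ms stability window trigger a warning).
#' @param dwellJitter half-width (ms) of the uniform jitter applied to
#'   each segment's target dwell (default 20).
#' @param carrierFreq oscillatory carrier frequency in Hz (default 10,
#'   alpha-band); the template's amplitude is modulated at this rate.
#' @param noiseSD sensor-noise standard deviation relative to unit
#'   template amplitude (default 0.6, giving the moderate labeling
#'   uncertainty typical of cleaned resting EEG).
#' @param subjectGain amplitude multiplier of the template signal
#'   (default 1); scales the subject's GFP and hence labeling certainty.
#' @param inversionProb per-template probability that a segment's
#'   topography appears with inverted polarity. Default: 0.5 for the
#'   first template and 0.05 for the rest, emulating the common empirical
#'   situation where one topography manifests with both polarities at GFP
#'   peaks while the others are polarity-dominant (the situation that
#'   makes one clustered map a polarity duplicate).
#' @param transitionMatrix k x k row-stochastic matrix with zero diagonal;
#'   default uniform over the other states.
#' @param seed integer seed.
#' @return list of class `synthConfig`.
#' @export
synthConfig <- function(nChannels = 64L, kTemplates = 4L, sfreq = 160,
                        duration = 30, meanDwell = 100, dwellJitter = 20,
                        carrierFreq = 10, noiseSD = 0.6, subjectGain = 1,
                        inversionProb = NULL, transitionMatrix = NULL,
                        seed = NULL) {
  k <- as.integer(kTemplates)
  stopifnot(nChannels >= 2L, k >= 1L, sfreq > 0, duration > 0,
            meanDwell > 0, dwellJitter >= 0, noiseSD >= 0, subjectGain > 0)
  if (meanDwell < 80 || meanDwell > 120) {
    warning("meanDwell ", meanDwell,
            " ms lies outside the typical 80-120 ms stability window")
  }
  if (is.null(inversionProb)) {
    inversionProb <- c(0.5, rep(0.05, max(0L, k - 1L)))[seq_len(k)]
  }
  inversionProb <- rep_len(inversionProb, k)
  stopifnot(all(inversionProb >= 0), all(inversionProb <= 1))
  if (is.null(transitionMatrix)) {
    transitionMatrix <- matrix(1 / max(1L, k - 1L), k, k)
    diag(transitionMatrix) <- 0
    if (k == 1L) transitionMatrix <- matrix(1, 1L, 1L)
  }
  transitionMatrix <- as.matrix(transitionMatrix)
  if (!all(dim(transitionMatrix) == k) ||
      any(abs(rowSums(transitionMatrix) - 1) > 1e-9) ||
      any(transitionMatrix < 0) ||
      (k > 1L && any(diag(transitionMatrix) != 0))) {
    stop("transitionMatrix must be k x k row-stochastic with zero diagonal")
  }
  structure(list(nChannels = as.integer(nChannels), kTemplates = k,
                 sfreq = sfreq, duration = duration, meanDwell = meanDwell,
                 dwellJitter = dwellJitter, carrierFreq = carrierFreq,
                 noiseSD = noiseSD, subjectGain = subjectGain,
                 inversionProb = inversionProb,
                 transitionMatrix = transitionMatrix, seed = seed),
            class = "synthConfig")
}

#' Generate smooth, mutually decorrelated template topographies
#'
#' Draws k Gaussian random fields with a squared-exponential covariance
#' over channel index (spatially smooth maps), mean-centers them,
#' orthogonalizes by Gram-Schmidt (pairwise correlation exactly 0 after
#' centering) and z-normalizes each row.
#'
#' @param nChannels number of channels (C).
#' @param k number of templates (k <= C).
#' @param seed integer seed.
#' @return k x C matrix; rows z-normalized, pairwise |r| < 0.3.
#' @export
generateTemplates <- function(nChannels, k, seed = NULL) {
  if (k > nChannels) stop("cannot generate more templates than channels")
  withSeed(seed, {
    idx <- seq_len(nChannels)
    ell <- max(2, nChannels / 8)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * ell^2))
    L <- chol(K + 1e-8 * diag(nChannels))
    raw <- matrix(stats::rnorm(k * nChannels), k, nChannels) %*% L
    raw <- raw - rowMeans(raw)
    # Gram-Schmidt on the centered maps: centered + orthogonal => r = 0
    for (i in seq_len(k)) {
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          raw[i, ] <- raw[i, ] -
            sum(raw[i, ] * raw[j, ]) / sum(raw[j, ]^2) * raw[j, ]
        }
      }
    }
    zNormalizeRows(raw)[, , drop = FALSE]
  })
}

#' Generate a synthetic EEG recording with known state structure
#'
#' States follow a first-order Markov chain; each segment's dwell is a
#' floored geometric draw (minimum 2 samples) around the jittered mean
#' dwell, so dwell times form a distribution rather than a comb. Within a
#' segment the active template is amplitude-modulated by a rectified
#' sinusoidal carrier with random phase, with the segment's polarity
#' flipped with per-template probability `inversionProb`; Gaussian sensor
#' noise is added. GFP peaks therefore occur near carrier extrema, where
#' the topographic SNR is maximal.
#'
#' @param cfg a [synthConfig()].
#' @param templates optional k x C template matrix (e.g. shared across a
#'   cohort); generated from the config seed when `NULL`.
#' @param subjectID,condition metadata tags for the recording.
#' @return list with `recording` (an [EEGRecording-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @export
generateRecording <- function(cfg, templates = NULL, subjectID = "synthetic",
                              condition = "unknown") {
  stopifnot(inherits(cfg, "synthConfig"))
  k <- cfg$kTemplates
  Tn <- as.integer(round(cfg$duration * cfg$sfreq))
  seeds <- childSeeds(if (is.null(cfg$seed)) NULL else cfg$seed, 2L)
  if (is.null(templates)) {
    templates <- generateTemplates(cfg$nChannels, k, seed = seeds[[1L]])
  }
  stopifnot(nrow(templates) == k, ncol(templates) == cfg$nChannels)

  withSeed(seeds[[2L]], {
    meanDwellSamples <- cfg$meanDwell / 1000 * cfg$sfreq
    jitterSamples <- cfg$dwellJitter / 1000 * cfg$sfreq

    state <- sample.int(k, 1L)
    starts <- integer(0L); ends <- integer(0L)
    states <- integer(0L); signs <- integer(0L)
    pos <- 1L
    while (pos <= Tn) {
      target <- meanDwellSamples +
        stats::runif(1L, -jitterSamples, jitterSamples)
      p <- 1 / max(target - 1, 1)
      dwell <- 2L + stats::rgeom(1L, p)
      end <- min(pos + dwell - 1L, Tn)
      starts <- c(starts, pos); ends <- c(ends, end)
      states <- c(states, state)
      flip <- stats::runif(1L) < cfg$inversionProb[state]
      signs <- c(signs, if (flip) -1L else 1L)
      pos <- end + 1L
      if (k > 1L) {
        state <- sample.int(k, 1L, prob = cfg$transitionMatrix[state, ])
      }
    }

    tSec <- (seq_len(Tn) - 1L) / cfg$sfreq
    stateSeq <- integer(Tn)
    X <- matrix(0, cfg$nChannels, Tn)
    for (s in seq_along(starts)) {
      idx <- starts[s]:ends[s]
      stateSeq[idx] <- states[s]
      phi <- stats::runif(1L, 0, 2 * pi)
      env <- abs(sin(2 * pi * cfg$carrierFreq * tSec[idx] + phi))
      X[, idx] <- cfg$subjectGain * signs[s] *
        tcrossprod(templates[states[s], ], env)
    }
    if (cfg$noiseSD > 0) {
      X <- X + stats::rnorm(length(X), sd = cfg$noiseSD)
    }

    rec <- EEGRecording(X, sfreq = cfg$sfreq, subjectID = subjectID,
                        condition = condition, reference = "as_recorded")
    truth <- new("GroundTruth", stateSequence = stateSeq,
                 templates = templates,
                 segments = data.frame(start = starts, end = ends,
                                       state = states, sign = signs))
    list(recording = rec, truth = truth)
  })
}

#' Generate a cohort of synthetic subjects under condition profiles
#'
#' All subjects share one template set (generated from the base config's
#' seed). Each subject receives a gain drawn uniformly from `gainRange`,
#' and one recording per condition profile; the default profiles contrast
#' a "real"-movement-like condition (longer dwells, lower noise) with an
#' "imagined"-like condition (shorter dwells, higher noise). All seeds
#' derive deterministically from the base seed.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param baseCfg a [synthConfig()] providing the shared parameters and
#'   base seed.
#' @param gainRange length-2 numeric range of per-subject gains.
#' @param conditionProfiles named list of config overrides per condition;
#'   names must be valid recording conditions.
#' @return list of entries `list(recording, truth)`, named
#'   `<subject>.<condition>`, plus attributes `"templates"` and
#'   `"gains"`.
#' @export
generateCohort <- function(nSubjects, baseCfg = synthConfig(),
                           gainRange = c(0.5, 2),
                           conditionProfiles = list(
                             real = list(meanDwell = 110, noiseSD = 0.5),
                             imagined = list(meanDwell = 70, noiseSD = 0.7))) {
  stopifnot(nSubjects >= 1L)
  if (length(gainRange) != 2L || diff(range(gainRange)) < 0 ||
      any(gainRange <= 0)) {
    stop("gainRange must be a positive length-2 range")
  }
  templates <- generateTemplates(baseCfg$nChannels, baseCfg$kTemplates,
                                 seed = baseCfg$seed)
  nCond <- length(conditionProfiles)
  seeds <- childSeeds(baseCfg$seed, nSubjects * nCond + 1L)
  gains <- withSeed(seeds[[1L]],
                    stats::runif(nSubjects, gainRange[1L], gainRange[2L]))

  out <- list()
  si <- 1L
  for (i in seq_len(nSubjects)) {
    sid <- sprintf("S%02d", i)
    for (cond in names(conditionProfiles)) {
      cfg <- baseCfg
      for (nm in names(conditionProfiles[[cond]])) {
        cfg[[nm]] <- conditionProfiles[[cond]][[nm]]
      }
      cfg$subjectGain <- gains[i]
      cfg$seed <- seeds[[1L + si]]
      out[[paste(sid, cond, sep = ".")]] <-
        generateRecording(cfg, templates = templates, subjectID = sid,
                          condition = cond)
      si <- si + 1L
    }
  }
  structure(out, templates = templates, gains = gains)
}

#' Score template and label recovery against ground truth
#'
#' Matches estimated templates to the true templates by the optimal
#' one-to-one assignment maximizing total absolute correlation (polarity
#' invariant). Reports the matched |r| per true template and, when an
#' estimated per-timepoint label sequence is supplied, the timepoint
#' label accuracy after mapping estimated labels through the assignment.
#' Differing template counts are handled by padding the report with
#' unmatched entries.
#'
#' @param estimated a [TemplateSet-class].
#' @param truth a [GroundTruth-class] with the same channel count.
#' @param labels optional integer vector of estimated per-timepoint
#'   labels (NA allowed), same length as the truth state sequence.
#' @return list: `matches` (data.frame `truthId`, `estimateId`,
#'   `absCor`), `accuracy` (NA without `labels`).
#' @export
scoreRecovery <- function(estimated, truth, labels = NULL) {
  stopifnot(is(estimated, "TemplateSet"), is(truth, "GroundTruth"))
  E <- estimated@maps
  Tm <- truth@templates
  if (ncol(E) != ncol(Tm)) stop("channel count mismatch")
  kE <- nrow(E); kT <- nrow(Tm)
  R <- abs(rowCorMatrix(E, Tm))
  n <- max(kE, kT)
  S <- matrix(0, n, n)
  S[seq_len(kE), seq_len(kT)] <- R
  fit <- solveAssignment(S)       # estimate row i -> column fit$perm[i]

  estToTruth <- rep(NA_integer_, kE)
  for (i in seq_len(kE)) {
    j <- fit$perm[i]
    if (j <= kT) estToTruth[i] <- j
  }
  matches <- data.frame(truthId = seq_len(kT),
                        estimateId = rep(NA_integer_, kT),
                        absCor = rep(NA_real_, kT))
  for (i in seq_len(kE)) {
    j <- estToTruth[i]
    if (!is.na(j)) {
      matches$estimateId[j] <- i
      matches$absCor[j] <- R[i, j]
    }
  }

  accuracy <- NA_real_
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(truth@stateSequence))
    mapped <- rep(NA_integer_, length(labels))
    okLab <- !is.na(labels)
    mapped[okLab] <- estToTruth[labels[okLab]]
    ok <- !is.na(mapped)
    if (any(ok)) {
      accuracy <- mean(mapped[ok] == truth@stateSequence[ok])
    }
  }
  list(matches = matches, accuracy = accuracy)
}
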