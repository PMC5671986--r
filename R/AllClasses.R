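#' @import methods
NULL

.CONDITIONS <- c("real", "imagined", "unknown")
.REFERENCES <- c("as_recorded", "average")

#' EEGRecording: a multichannel EEG signal
#'
#' Container for a channels-by-timepoints EEG matrix (microvolts) together
#' with its sampling rate, channel labels and subject/condition metadata.
#' All computation in the package operates on this class; recordings are
#' conventionally re-referenced to the common average on load (see
#' [rereferenceAverage()]), which leaves the global field power unchanged.
#'
#' @slot data numeric matrix, channels x timepoints, all values finite.
#' @slot sfreq sampling frequency in Hz (> 0).
#' @slot channelNames character vector, one unique name per row of `data`.
#' @slot subjectID subject identifier.
#' @slot condition one of `"real"`, `"imagined"`, `"unknown"`.
#' @slot reference one of `"as_recorded"`, `"average"`.
#'
#' @seealso [readEDF()], [readMatrix()], [computeGFP()]
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    sfreq = "numeric",
    channelNames = "character",
    subjectID = "character",
    condition = "character",
    reference = "character"
  ),
  prototype(
    subjectID = "unknown",
    condition = "unknown",
    reference = "as_recorded"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "data must be a numeric matrix")
  if (nrow(d) < 2L) msg <- c(msg, "at least 2 channels are required")
  if (ncol(d) < 1L) msg <- c(msg, "at least 1 timepoint is required")
  if (any(!is.finite(d))) msg <- c(msg, "data contains non-finite values")
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0) {
    msg <- c(msg, "sfreq must be a single positive number")
  }
  if (length(object@channelNames) != nrow(d)) {
    msg <- c(msg, "channelNames length must equal the number of channels")
  }
  if (anyDuplicated(object@channelNames)) {
    msg <- c(msg, "channelNames must be unique")
  }
  if (!object@condition %in% .CONDITIONS) {
    msg <- c(msg, sprintf("condition must be one of: %s",
                          paste(.CONDITIONS, collapse = ", ")))
  }
  if (!object@reference %in% .REFERENCES) {
    msg <- c(msg, sprintf("reference must be one of: %s",
                          paste(.REFERENCES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x timepoints numeric matrix (microvolts).
#' @param sfreq sampling frequency in Hz.
#' @param channelNames channel labels; defaults to `Ch1..ChN`.
#' @param subjectID subject identifier string.
#' @param condition `"real"`, `"imagined"` or `"unknown"`.
#' @param reference `"as_recorded"` or `"average"`.
#' @return an [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(40), 4, 10), sfreq = 160)
#' samplingRate(rec)
#' @export
EEGRecording <- function(data, sfreq, channelNames = NULL,
                         subjectID = "unknown", condition = "unknown",
                         reference = "as_recorded") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channelNames)) {
    channelNames <- if (!is.null(rownames(data))) rownames(data)
      else paste0("Ch", seq_len(nrow(data)))
  }
  new("EEGRecording", data = data, sfreq = as.numeric(sfreq),
      channelNames = as.character(channelNames),
      subjectID = as.character(subjectID), condition = condition,
      reference = reference)
}

#' TemplateSet: microstate template maps
#'
#' A set of k template topographies (cluster centroids, z-normalized per
#' map) with canonical labels, provenance and a log of polarity merges.
#'
#' @slot maps k x C numeric matrix; each row mean 0, sd 1 across channels.
#' @slot labels integer template ids.
#' @slot method clustering method that produced the maps ("kmeans", "fcm",
#'   "truth", ...).
#' @slot condition data condition the maps were derived from.
#' @slot configHash hash of the producing configuration (provenance).
#' @slot mergeLog data.frame with columns `kept`, `absorbed`, `correlation`
#'   recording polarity-duplicate merges.
#' @exportClass TemplateSet
setClass("TemplateSet",
  representation(
    maps = "matrix",
    labels = "integer",
    method = "character",
    condition = "character",
    configHash = "character",
    mergeLog = "data.frame"
  ),
  prototype(
    method = "unknown", condition = "unknown", configHash = "",
    mergeLog = data.frame(kept = integer(), absorbed = integer(),
                          correlation = numeric())
  )
)

setValidity("TemplateSet", function(object) {
  msg <- character()
  m <- object@maps
  if (nrow(m) < 1L) msg <- c(msg, "at least one template map is required")
  if (any(!is.finite(m))) msg <- c(msg, "maps contain non-finite values")
  if (length(object@labels) != nrow(m)) {
    msg <- c(msg, "labels length must equal the number of maps")
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  if (any(abs(mu) > 1e-6) || any(abs(sdv - 1) > 1e-6)) {
    msg <- c(msg, "each map must be z-normalized (mean 0, sd 1) across channels")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TemplateSet
#'
#' Rows are z-normalized across channels on construction.
#'
#' @param maps k x C matrix of template topographies.
#' @param labels integer ids (default `1:k`).
#' @param method,condition,configHash provenance strings.
#' @param mergeLog polarity-merge log (see [mergePolarityDuplicates()]).
#' @return a [TemplateSet-class].
#' @export
TemplateSet <- function(maps, labels = seq_len(nrow(maps)),
                        method = "unknown", condition = "unknown",
                        configHash = "",
                        mergeLog = data.frame(kept = integer(),
                                              absorbed = integer(),
                                              correlation = numeric())) {
  maps <- zNormalizeRows(as.matrix(maps))
  new("TemplateSet", maps = maps, labels = as.integer(labels),
      method = method, condition = condition, configHash = configHash,
      mergeLog = mergeLog)
}

#' ClusterResult: output of K-means or fuzzy C-means
#'
#' Holds the centroids (template maps before normalization), hard labels,
#' the membership matrix U (one-hot for hard K-means), the final objective
#' J, its per-iteration trace for the winning replicate, and the final
#' objective of every replicate.
#'
#' @slot centroids k x C matrix of cluster centroids.
#' @slot hardLabels length-N integer labels in 1..k.
#' @slot U N x k membership matrix; rows sum to 1.
#' @slot objective final value of the minimized objective J.
#' @slot objectiveTrace per-iteration J of the winning replicate
#'   (non-increasing).
#' @slot replicateObjectives final J per replicate.
#' @slot method `"kmeans"` or `"fcm"`.
#' @slot config the [clusterConfig()] list used.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(
    centroids = "matrix",
    hardLabels = "integer",
    U = "matrix",
    objective = "numeric",
    objectiveTrace = "numeric",
    replicateObjectives = "numeric",
    method = "character",
    config = "list"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  k <- nrow(object@centroids)
  N <- length(object@hardLabels)
  if (!all(dim(object@U) == c(N, k))) {
    msg <- c(msg, "U must be N x k")
  } else {
    if (any(object@U < -1e-12) || any(object@U > 1 + 1e-12)) {
      msg <- c(msg, "memberships must lie in [0, 1]")
    }
    if (any(abs(rowSums(object@U) - 1) > 1e-9)) {
      msg <- c(msg, "membership rows must sum to 1 (within 1e-9)")
    }
    if (N > 0 && !identical(object@hardLabels,
                            max.col(object@U, ties.method = "first"))) {
      msg <- c(msg, "hardLabels must equal the row-wise argmax of U")
    }
  }
  if (length(object@replicateObjectives) &&
      object@objective > min(object@replicateObjectives) + 1e-9) {
    msg <- c(msg, "objective must be the minimum over replicates")
  }
  tr <- object@objectiveTrace
  if (length(tr) > 1L && any(diff(tr) > 1e-9 * max(1, tr[1L]))) {
    msg <- c(msg, "objectiveTrace must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' StateSequence: probabilistic microstate labels over time
#'
#' Per-timepoint probability vectors over microstates, with the
#' maximum-likelihood (MLE) label, its probability, and a mask of
#' timepoints that received a genuine label (zero-variance timepoints are
#' given the uniform fallback and marked unlabeled).
#'
#' @slot probs T x k matrix; each row sums to 1.
#' @slot mleLabel length-T integer labels (NA where unlabeled).
#' @slot mleProb length-T maximum probabilities.
#' @slot labeled logical mask of genuinely labeled timepoints.
#' @slot templateRef provenance string of the template set / model.
#' @exportClass StateSequence
setClass("StateSequence",
  representation(
    probs = "matrix",
    mleLabel = "integer",
    mleProb = "numeric",
    labeled = "logical",
    templateRef = "character"
  ),
  prototype(templateRef = "")
)

setValidity("StateSequence", function(object) {
  msg <- character()
  P <- object@probs
  Tn <- nrow(P)
  if (any(!is.finite(P)) || any(P < -1e-12)) {
    msg <- c(msg, "probabilities must be finite and non-negative")
  }
  if (Tn > 0 && any(abs(rowSums(P) - 1) > 1e-9)) {
    msg <- c(msg, "probability rows must sum to 1 (within 1e-9)")
  }
  if (length(object@mleLabel) != Tn || length(object@mleProb) != Tn ||
      length(object@labeled) != Tn) {
    msg <- c(msg, "mleLabel, mleProb and labeled must have one entry per row")
  } else if (Tn > 0) {
    lab <- object@labeled
    if (any(lab)) {
      expLbl <- max.col(P[lab, , drop = FALSE], ties.method = "first")
      expPrb <- P[cbind(which(lab), expLbl)]
      if (!identical(object@mleLabel[lab], expLbl) ||
          any(abs(object@mleProb[lab] - expPrb) > 1e-12)) {
        msg <- c(msg, "mleLabel/mleProb must be the row-wise argmax/max of probs")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

.StateSequence <- function(probs, labeled = rep(TRUE, nrow(probs)),
                           templateRef = "") {
  Tn <- nrow(probs)
  mleLabel <- rep(NA_integer_, Tn)
  mleProb <- rep(NA_real_, Tn)
  if (any(labeled)) {
    lbl <- max.col(probs[labeled, , drop = FALSE], ties.method = "first")
    mleLabel[labeled] <- lbl
    mleProb[labeled] <- probs[cbind(which(labeled), lbl)]
  }
  new("StateSequence", probs = probs, mleLabel = mleLabel, mleProb = mleProb,
      labeled = labeled, templateRef = templateRef)
}

#' MLPModel: a trained softmax multilayer perceptron
#'
#' One tanh hidden layer and a softmax output layer; trained with a
#' cross-entropy loss (see [trainMLP()]). The training report records the
#' per-epoch train/validation loss, the chosen (best-validation) epoch, the
#' data split and the seed, so that evaluation can be reproduced.
#'
#' @slot W1,b1 input-to-hidden weights (C x H) and biases (H).
#' @slot W2,b2 hidden-to-output weights (H x k) and biases (k).
#' @slot classIds integer ids of the output classes, in output order.
#' @slot config the [mlpConfig()] used.
#' @slot trainingReport list: `trainLoss`, `valLoss`, `chosenEpoch`,
#'   `epochs`, `splits` (list of train/val/test index vectors), `seed`.
#' @exportClass MLPModel
setClass("MLPModel",
  representation(
    W1 = "matrix", b1 = "numeric",
    W2 = "matrix", b2 = "numeric",
    classIds = "integer",
    config = "list",
    trainingReport = "list"
  )
)

setValidity("MLPModel", function(object) {
  msg <- character()
  if (ncol(object@W1) != length(object@b1)) {
    msg <- c(msg, "hidden layer width mismatch between W1 and b1")
  }
  if (nrow(object@W2) != ncol(object@W1)) {
    msg <- c(msg, "W1/W2 dimension mismatch")
  }
  if (ncol(object@W2) != length(object@b2) ||
      ncol(object@W2) != length(object@classIds)) {
    msg <- c(msg, "output width mismatch between W2, b2 and classIds")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generative state structure of a synthetic recording
#'
#' @slot stateSequence per-timepoint true template id.
#' @slot templates k x C matrix of the true (z-normalized) topographies.
#' @slot segments data.frame with columns `start`, `end`, `state`, `sign`
#'   (contiguous segments covering the recording).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    stateSequence = "integer",
    templates = "matrix",
    segments = "data.frame"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  k <- nrow(object@templates)
  s <- object@stateSequence
  if (length(s) && (min(s) < 1L || max(s) > k)) {
    msg <- c(msg, "state ids must lie in 1..k")
  }
  seg <- object@segments
  if (nrow(seg)) {
    if (seg$start[1L] != 1L || seg$end[nrow(seg)] != length(s) ||
        (nrow(seg) > 1L && any(seg$start[-1L] != seg$end[-nrow(seg)] + 1L))) {
      msg <- c(msg, "segments must be contiguous and cover the recording")
    }
  }
  if (length(msg)) msg else TRUE
})
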