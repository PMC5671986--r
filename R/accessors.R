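# Accessor and show methods for the package classes.

#' @rdname EEGRecording-class
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@sfreq)

#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)

#' @rdname EEGRecording-class
#' @export
setMethod("subjectID", "EEGRecording", function(x) x@subjectID)

#' @rdname EEGRecording-class
#' @export
setMethod("subjectCondition", "EEGRecording", function(x) x@condition)

#' @rdname EEGRecording-class
#' @export
setMethod("referenceType", "EEGRecording", function(x) x@reference)

#' @rdname EEGRecording-class
#' @export
setMethod("dim", "EEGRecording", function(x) dim(x@data))

setMethod("show", "EEGRecording", function(object) {
  d <- dim(object@data)
  cat(sprintf("EEGRecording: %d channels x %d timepoints @ %g Hz (%.2f s)\n",
              d[1L], d[2L], object@sfreq, d[2L] / object@sfreq))
  cat(sprintf("  subject: %s | condition: %s | reference: %s\n",
              object@subjectID, object@condition, object@reference))
})

#' @rdname TemplateSet-class
#' @export
setMethod("templateMaps", "TemplateSet", function(x) x@maps)

#' @rdname TemplateSet-class
#' @export
setMethod("templateLabels", "TemplateSet", function(x) x@labels)

#' @rdname TemplateSet-class
#' @export
setMethod("mergeLog", "TemplateSet", function(x) x@mergeLog)

#' @rdname nStates
#' @export
setMethod("nStates", "TemplateSet", function(x) nrow(x@maps))

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d maps x %d channels (%s, %s)\n",
              nrow(object@maps), ncol(object@maps), object@method,
              object@condition))
  if (nrow(object@mergeLog)) {
    cat(sprintf("  polarity merges: %d (min r = %.3f)\n",
                nrow(object@mergeLog), min(object@mergeLog$correlation)))
  }
})

#' @rdname ClusterResult-class
#' @export
setMethod("clusterCentroids", "ClusterResult", function(x) x@centroids)

#' @rdname ClusterResult-class
#' @export
setMethod("hardLabels", "ClusterResult", function(x) x@hardLabels)

#' @rdname ClusterResult-class
#' @export
setMethod("membershipMatrix", "ClusterResult", function(x) x@U)

#' @rdname ClusterResult-class
#' @export
setMethod("objectiveValue", "ClusterResult", function(x) x@objective)

#' @rdname ClusterResult-class
#' @export
setMethod("objectiveTrace", "ClusterResult", function(x) x@objectiveTrace)

#' @rdname nStates
#' @export
setMethod("nStates", "ClusterResult", function(x) nrow(x@centroids))

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult (%s): k = %d, N = %d, J = %.6g\n",
              object@method, nrow(object@centroids),
              length(object@hardLabels), object@objective))
  cat(sprintf("  replicates: %d | iterations: %d\n",
              length(object@replicateObjectives),
              length(object@objectiveTrace)))
})

#' @rdname StateSequence-class
#' @export
setMethod("stateProbs", "StateSequence", function(x) x@probs)

#' @rdname StateSequence-class
#' @export
setMethod("mleLabels", "StateSequence", function(x) x@mleLabel)

#' @rdname StateSequence-class
#' @export
setMethod("mleProbs", "StateSequence", function(x) x@mleProb)

#' @rdname StateSequence-class
#' @export
setMethod("labeledMask", "StateSequence", function(x) x@labeled)

#' @rdname nStates
#' @export
setMethod("nStates", "StateSequence", function(x) ncol(x@probs))

#' @rdname StateSequence-class
#' @export
setMethod("length", "StateSequence", function(x) nrow(x@probs))

setMethod("show", "StateSequence", function(object) {
  n <- nrow(object@probs)
  lab <- sum(object@labeled)
  cat(sprintf("StateSequence: %d timepoints, %d states (%d labeled)\n",
              n, ncol(object@probs), lab))
  if (lab) {
    cat(sprintf("  mean MLE probability: %.3f\n",
                mean(object@mleProb[object@labeled])))
  }
})

#' @rdname GroundTruth-class
#' @export
setMethod("stateSequence", "GroundTruth", function(x) x@stateSequence)

#' @rdname GroundTruth-class
#' @export
setMethod("templateMaps", "GroundTruth", function(x) x@templates)

#' @rdname nStates
#' @export
setMethod("nStates", "GroundTruth", function(x) nrow(x@templates))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d states over %d timepoints, %d segments\n",
              nrow(object@templates), length(object@stateSequence),
              nrow(object@segments)))
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel: %d -> %d (tanh) -> %d (softmax)\n",
              nrow(object@W1), ncol(object@W1), ncol(object@W2)))
  rep <- object@trainingReport
  if (length(rep)) {
    cat(sprintf("  trained %d epochs, best validation at epoch %d (val loss %.4f)\n",
                rep$epochs, rep$chosenEpoch,
                rep$valLoss[rep$chosenEpoch]))
  }
})
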