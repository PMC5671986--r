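#' @rdname EEGRecording-class
#' @param object,x an object.
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EEGRecording-class
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname EEGRecording-class
#' @export
setGeneric("subjectCondition", function(x) standardGeneric("subjectCondition"))

#' @rdname EEGRecording-class
#' @export
setGeneric("referenceType", function(x) standardGeneric("referenceType"))

#' @rdname TemplateSet-class
#' @param x an object.
#' @export
setGeneric("templateMaps", function(x) standardGeneric("templateMaps"))

#' @rdname TemplateSet-class
#' @export
setGeneric("templateLabels", function(x) standardGeneric("templateLabels"))

#' @rdname TemplateSet-class
#' @export
setGeneric("mergeLog", function(x) standardGeneric("mergeLog"))

#' @rdname ClusterResult-class
#' @param x an object.
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))

#' @rdname ClusterResult-class
#' @export
setGeneric("hardLabels", function(x) standardGeneric("hardLabels"))

#' @rdname ClusterResult-class
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @rdname ClusterResult-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname ClusterResult-class
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname StateSequence-class
#' @param x an object.
#' @export
setGeneric("stateProbs", function(x) standardGeneric("stateProbs"))

#' @rdname StateSequence-class
#' @export
setGeneric("mleLabels", function(x) standardGeneric("mleLabels"))

#' @rdname StateSequence-class
#' @export
setGeneric("mleProbs", function(x) standardGeneric("mleProbs"))

#' @rdname StateSequence-class
#' @export
setGeneric("labeledMask", function(x) standardGeneric("labeledMask"))

#' @rdname GroundTruth-class
#' @param x an object.
#' @export
setGeneric("stateSequence", function(x) standardGeneric("stateSequence"))

#' Number of states/templates/clusters represented by an object
#' @param x an object.
#' @return integer count.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
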