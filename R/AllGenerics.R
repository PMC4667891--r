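#' @rdname featureSpace
#' @export
setGeneric("featureSpace", function(x) standardGeneric("featureSpace"))

#' @rdname nPatterns
#' @export
setGeneric("nPatterns", function(space) standardGeneric("nPatterns"))

#' @rdname nFeatures
#' @export
setGeneric("nFeatures", function(space) standardGeneric("nFeatures"))

#' @rdname cardinalities
#' @export
setGeneric("cardinalities", function(space) standardGeneric("cardinalities"))

#' @rdname independentParamCount
#' @export
setGeneric("independentParamCount",
  function(space) standardGeneric("independentParamCount"))

#' @rdname fullParamCount
#' @export
setGeneric("fullParamCount", function(space) standardGeneric("fullParamCount"))

#' @rdname patternLabels
#' @export
setGeneric("patternLabels", function(space) standardGeneric("patternLabels"))

#' @rdname expandToFull
#' @export
setGeneric("expandToFull", function(sig) standardGeneric("expandToFull"))

#' @rdname sampleIDs
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname mutationCounts
#' @export
setGeneric("mutationCounts", function(x) standardGeneric("mutationCounts"))

#' @rdname totalMutations
#' @export
setGeneric("totalMutations", function(x) standardGeneric("totalMutations"))

#' @rdname signatures
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname memberships
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname logLikTrace
#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))

#' @rdname backgroundSignatureOf
#' @export
setGeneric("backgroundSignatureOf", function(x) standardGeneric("backgroundSignatureOf"))
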