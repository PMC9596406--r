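#' @rdname boldValues
#' @export
setGeneric("boldValues", function(x) standardGeneric("boldValues"))

#' @rdname repetitionTime
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname regionLabels
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname provenance
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname nFrames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nRegions
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname curveScales
#' @export
setGeneric("curveScales", function(x) standardGeneric("curveScales"))

#' @rdname curveValues
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname scalingExponent
#' @export
setGeneric("scalingExponent", function(x) standardGeneric("scalingExponent"))

#' @rdname dccValues
#' @export
setGeneric("dccValues", function(x) standardGeneric("dccValues"))

#' @rdname eigenvalues
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname eigenvectors
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname clusterLabels
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterOrder
#' @export
setGeneric("clusterOrder", function(x) standardGeneric("clusterOrder"))

#' @rdname ensembleConfig
#' @export
setGeneric("ensembleConfig", function(x) standardGeneric("ensembleConfig"))

#' @rdname fitScaling
#' @export
setGeneric("fitScaling",
  function(curve, fitRange = NULL) standardGeneric("fitScaling"))
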