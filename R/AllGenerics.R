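## Accessor generics. Slot access from user code goes through these.

#' @rdname LaneProfile-class
#' @param x object
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname LaneProfile-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname LaneProfile-class
#' @export
setGeneric("markerPositions", function(x) standardGeneric("markerPositions"))
#' @rdname LaneProfile-class
#' @export
setGeneric("markerSizes", function(x) standardGeneric("markerSizes"))

#' @rdname LengthEstimate-class
#' @param x object
#' @export
setGeneric("lengthBp", function(x) standardGeneric("lengthBp"))
#' @rdname LengthEstimate-class
#' @export
setGeneric("smearRange", function(x) standardGeneric("smearRange"))

#' @rdname ExpressionBundle-class
#' @param x object
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))
#' @rdname ExpressionBundle-class
#' @export
setGeneric("detectionCalls", function(x) standardGeneric("detectionCalls"))
#' @rdname ExpressionBundle-class
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname SamResult-class
#' @param x object
#' @export
setGeneric("samScores", function(x) standardGeneric("samScores"))
#' @rdname SamResult-class
#' @export
setGeneric("samQValues", function(x) standardGeneric("samQValues"))
#' @rdname SamResult-class
#' @export
setGeneric("significantGenes", function(x) standardGeneric("significantGenes"))
#' @rdname SamResult-class
#' @export
setGeneric("samS0", function(x) standardGeneric("samS0"))

#' @rdname StressDESets-class
#' @param x object
#' @export
setGeneric("deSets", function(x) standardGeneric("deSets"))
#' @rdname StressDESets-class
#' @export
setGeneric("specificSets", function(x) standardGeneric("specificSets"))
#' @rdname StressDESets-class
#' @export
setGeneric("directionSpecificSets",
           function(x) standardGeneric("directionSpecificSets"))

#' @rdname GeneNetwork-class
#' @param x object
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))
#' @rdname GeneNetwork-class
#' @export
setGeneric("tlmGenes", function(x) standardGeneric("tlmGenes"))
#' @rdname GeneNetwork-class
#' @param stress stress label; if missing, the full named list
#' @export
setGeneric("deGenes", function(x, stress) standardGeneric("deGenes"))

#' @rdname ProximityResult-class
#' @param x object
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname ProximityResult-class
#' @export
setGeneric("proximalDistances",
           function(x) standardGeneric("proximalDistances"))
#' @rdname ProximityResult-class
#' @export
setGeneric("backgroundDistances",
           function(x) standardGeneric("backgroundDistances"))
#' @rdname ProximityResult-class
#' @export
setGeneric("excludedPairs", function(x) standardGeneric("excludedPairs"))

#' @rdname RegressionFit-class
#' @param x object
#' @export
setGeneric("fitScale", function(x) standardGeneric("fitScale"))

#' @rdname EnrichmentResult-class
#' @param x object
#' @export
setGeneric("foldValue", function(x) standardGeneric("foldValue"))

#' @rdname SyntheticTruth-class
#' @param x object
#' @export
setGeneric("plantedDeGenes", function(x) standardGeneric("plantedDeGenes"))
#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedProximal", function(x) standardGeneric("plantedProximal"))
#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedOutliers", function(x) standardGeneric("plantedOutliers"))
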