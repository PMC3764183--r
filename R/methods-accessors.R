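## Accessors and show methods.

#' @rdname LaneProfile-class
#' @export
setMethod("positions", "LaneProfile", function(x) x@positions)
#' @rdname LaneProfile-class
#' @export
setMethod("intensities", "LaneProfile", function(x) x@intensities)
#' @rdname LaneProfile-class
#' @export
setMethod("markerPositions", "LaneProfile", function(x) x@markerPositions)
#' @rdname LaneProfile-class
#' @export
setMethod("markerSizes", "LaneProfile", function(x) x@markerSizes)

setMethod("show", "LaneProfile", function(object) {
  cat(sprintf(
    "LaneProfile: %d points over [%g, %g]; markers %g bp @ %g, %g bp @ %g\n",
    length(object@positions), min(object@positions), max(object@positions),
    object@markerSizes[1], object@markerPositions[1],
    object@markerSizes[2], object@markerPositions[2]))
})

setMethod("show", "SizeCalibration", function(object) {
  cat(sprintf("SizeCalibration: log10(bp) = %.6g + (%.6g) * position\n",
              object@intercept, object@slope))
})

#' @rdname LengthEstimate-class
#' @export
setMethod("lengthBp", "LengthEstimate", function(x) x@length)
#' @rdname LengthEstimate-class
#' @export
setMethod("smearRange", "LengthEstimate", function(x)
  c(lo = x@smearLo, hi = x@smearHi))

setMethod("show", "LengthEstimate", function(object) {
  cat(sprintf("LengthEstimate: %.1f bp (smear %.1f-%.1f bp)\n",
              object@length, object@smearLo, object@smearHi))
})

#' @rdname ExpressionBundle-class
#' @export
setMethod("exprsMatrix", "ExpressionBundle", function(x)
  SummarizedExperiment::assay(x, "exprs"))
#' @rdname ExpressionBundle-class
#' @export
setMethod("detectionCalls", "ExpressionBundle", function(x)
  SummarizedExperiment::assay(x, "calls"))
#' @rdname ExpressionBundle-class
#' @export
setMethod("sampleConditions", "ExpressionBundle", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$condition, colnames(x)))

#' @rdname SamResult-class
#' @export
setMethod("samScores", "SamResult", function(x) x@d)
#' @rdname SamResult-class
#' @export
setMethod("samQValues", "SamResult", function(x) x@q)
#' @rdname SamResult-class
#' @export
setMethod("significantGenes", "SamResult", function(x) x@significant)
#' @rdname SamResult-class
#' @export
setMethod("samS0", "SamResult", function(x) x@s0)

setMethod("show", "SamResult", function(object) {
  cat(sprintf(
    "SamResult: %d genes, s0 = %.4g, %d significant at FDR < %g (%d perms)\n",
    length(object@d), object@s0, length(object@significant),
    object@fdrThreshold, object@nPerm))
})

#' @rdname StressDESets-class
#' @export
setMethod("deSets", "StressDESets", function(x) x@de)
#' @rdname StressDESets-class
#' @export
setMethod("specificSets", "StressDESets", function(x) x@specific)
#' @rdname StressDESets-class
#' @export
setMethod("directionSpecificSets", "StressDESets",
          function(x) x@directionSpecific)

setMethod("show", "StressDESets", function(object) {
  cat("StressDESets:\n")
  for (s in names(object@de))
    cat(sprintf("  %s: %d DE, %d stress-specific\n", s,
                length(object@de[[s]]), length(object@specific[[s]])))
  for (g in names(object@directionSpecific))
    cat(sprintf("  direction %s: %d genes\n", g,
                length(object@directionSpecific[[g]])))
})

#' @rdname GeneNetwork-class
#' @export
setMethod("networkGraph", "GeneNetwork", function(x) x@graph)
#' @rdname GeneNetwork-class
#' @export
setMethod("tlmGenes", "GeneNetwork", function(x) x@tlm)
#' @rdname GeneNetwork-class
#' @export
setMethod("deGenes", "GeneNetwork", function(x, stress) {
  if (missing(stress)) return(x@deByStress)
  if (!stress %in% names(x@deByStress))
    stop("no DE flags for stress '", stress, "'")
  x@deByStress[[stress]]
})

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf(
    "GeneNetwork: %d nodes, %d edges; %d TLM genes; DE flags for: %s\n",
    igraph::vcount(object@graph), igraph::ecount(object@graph),
    length(object@tlm),
    if (length(object@deByStress))
      paste(names(object@deByStress), collapse = ", ") else "(none)"))
})

#' @rdname ProximityResult-class
#' @export
setMethod("pValue", "ProximityResult", function(x) x@p)
#' @rdname ProximityResult-class
#' @export
setMethod("proximalDistances", "ProximityResult", function(x) x@distA)
#' @rdname ProximityResult-class
#' @export
setMethod("backgroundDistances", "ProximityResult", function(x) x@distB)
#' @rdname ProximityResult-class
#' @export
setMethod("excludedPairs", "ProximityResult", function(x) x@nExcludedPairs)

setMethod("show", "ProximityResult", function(object) {
  cat(sprintf(
    "ProximityResult (%s):\n  n_A = %d pairs (median d = %g), n_B = %d pairs (median d = %g)\n  U = %g, p = %.3g (%s), %d unreachable pairs excluded\n",
    object@comparison, length(object@distA), median(object@distA),
    length(object@distB), median(object@distB),
    object@statistic, object@p, object@alternative, object@nExcludedPairs))
})

#' @rdname RegressionFit-class
#' @export
setMethod("coef", "RegressionFit", function(object)
  c(intercept = object@intercept, slope = object@slope))
#' @rdname RegressionFit-class
#' @export
setMethod("residuals", "RegressionFit", function(object) object@residuals)
#' @rdname RegressionFit-class
#' @export
setMethod("weights", "RegressionFit", function(object) object@weights)
#' @rdname RegressionFit-class
#' @export
setMethod("fitScale", "RegressionFit", function(x) x@scale)

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf(
    "RegressionFit: delta = %.4g * initial + %.4g, scale = %.4g bp (%s, %d iter)\n",
    object@slope, object@intercept, object@scale,
    if (object@converged) "converged" else "NOT converged", object@nIter))
})

#' @rdname EnrichmentResult-class
#' @export
setMethod("foldValue", "EnrichmentResult", function(x) x@fold)

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult [%s]: fold = %.3g (log2 = %.3g, spread = %.3g, n = %d)\n",
    object@condition, object@fold, object@log2Fold, object@spread,
    object@nReplicates))
})

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedDeGenes", "SyntheticTruth", function(x) x@deGenes)
#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedProximal", "SyntheticTruth", function(x) x@plantedProximal)
#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedOutliers", "SyntheticTruth", function(x) x@screenOutliers)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth (seed %d): DE sets for %d stresses, %d proximal genes, outliers for %d screens, %d lane sizes\n",
    object@seed, length(object@deGenes), length(object@plantedProximal),
    length(object@screenOutliers), length(object@trueFragmentSizes)))
})
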