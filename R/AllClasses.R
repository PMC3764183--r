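#' @import methods
#' @importFrom stats median mad quantile rnorm runif sd qnorm pnorm pt
#'   lm.wfit coef residuals weights setNames
#' @importFrom utils combn read.delim write.table head
NULL

## ---------------------------------------------------------------------------
## Lane densitometry
## ---------------------------------------------------------------------------

#' LaneProfile: a 1-D gel-lane densitometry trace
#'
#' Intensity sampled along the migration axis of a Southern-blot lane,
#' together with the positions of the two size-marker bands (2044 and 779 bp
#' in the original assay) used to calibrate fragment sizes.
#'
#' @slot positions strictly increasing migration coordinates (arbitrary units)
#' @slot intensities non-negative signal, one value per position
#' @slot markerPositions migration coordinates of the two marker bands
#' @slot markerSizes fragment sizes of the two marker bands, in bp
#' @export
setClass("LaneProfile",
  representation(
    positions = "numeric",
    intensities = "numeric",
    markerPositions = "numeric",
    markerSizes = "numeric"
  )
)

setValidity("LaneProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@intensities))
    msg <- c(msg, "positions and intensities must have equal length")
  if (length(object@positions) >= 2 &&
      any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@markerPositions) != 2L ||
      length(object@markerSizes) != 2L)
    msg <- c(msg, "exactly two marker bands are required")
  if (length(object@markerSizes) == 2L &&
      (any(object@markerSizes <= 0) ||
       object@markerSizes[1] == object@markerSizes[2]))
    msg <- c(msg, "markerSizes must be distinct and positive")
  if (length(msg)) msg else TRUE
})

#' Construct a LaneProfile
#'
#' @param positions migration coordinates, strictly increasing
#' @param intensities non-negative intensities, same length as `positions`
#' @param markerPositions two marker-band migration coordinates
#' @param markerSizes two marker-band fragment sizes (bp)
#' @return a [LaneProfile-class] object
#' @examples
#' LaneProfile(1:10, rep(1, 10), c(2, 9), c(2044, 779))
#' @export
LaneProfile <- function(positions, intensities, markerPositions, markerSizes) {
  new("LaneProfile",
      positions = as.numeric(positions),
      intensities = as.numeric(intensities),
      markerPositions = as.numeric(markerPositions),
      markerSizes = as.numeric(markerSizes))
}

#' SizeCalibration: log-linear migration-to-size mapping
#'
#' The standard gel-electrophoresis approximation: log10(fragment size in bp)
#' is linear in migration distance. The line is anchored on the two marker
#' bands, so it reproduces both marker sizes exactly.
#'
#' @slot slope d(log10 bp) / d(position)
#' @slot intercept log10 bp at position 0
#' @export
setClass("SizeCalibration",
  representation(slope = "numeric", intercept = "numeric")
)

setValidity("SizeCalibration", function(object) {
  if (length(object@slope) != 1L || length(object@intercept) != 1L)
    return("slope and intercept must be scalars")
  if (object@slope == 0) return("slope must be nonzero")
  TRUE
})

#' LengthEstimate: telomere fragment length summary for one lane
#'
#' @slot length estimated fragment length (bp), the size at the
#'   intensity-weighted centroid of the smear
#' @slot smearLo lower bp bound of the detected smear
#' @slot smearHi upper bp bound of the detected smear
#' @slot background subtracted background intensity
#' @export
setClass("LengthEstimate",
  representation(length = "numeric", smearLo = "numeric",
                 smearHi = "numeric", background = "numeric")
)

setValidity("LengthEstimate", function(object) {
  if (!(object@smearLo <= object@length && object@length <= object@smearHi))
    return("smearLo <= length <= smearHi must hold")
  TRUE
})

## ---------------------------------------------------------------------------
## Expression
## ---------------------------------------------------------------------------

#' ExpressionBundle: normalized expression with detection calls
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with two assays:
#' `exprs` (normalized log-scale expression, genes x samples) and `calls`
#' (Affymetrix-style detection flags, one of `"P"`, `"M"`, `"A"`), and a
#' `condition` column in `colData` mapping each sample to its growth
#' condition (control or one of the stresses).
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("ExpressionBundle", contains = "SummarizedExperiment")

setValidity("ExpressionBundle", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("exprs", "calls") %in% an))
    return("assays 'exprs' and 'calls' are required")
  calls <- SummarizedExperiment::assay(object, "calls")
  if (!all(calls %in% c("P", "M", "A")))
    msg <- c(msg, "detection calls must be 'P', 'M' or 'A'")
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'condition' column")
  } else {
    tab <- table(cd$condition)
    if (any(tab < 2))
      msg <- c(msg, "every condition needs at least 2 samples")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionBundle
#'
#' @param exprs numeric matrix, genes x samples, normalized log-scale values;
#'   rownames are gene IDs, colnames sample IDs
#' @param calls character matrix of detection calls ("P"/"M"/"A"), same
#'   dimensions and dimnames as `exprs`
#' @param conditions character vector (or factor) of per-sample condition
#'   labels, length `ncol(exprs)`
#' @return an [ExpressionBundle-class]
#' @export
ExpressionBundle <- function(exprs, calls, conditions) {
  stopifnot(is.matrix(exprs), is.matrix(calls),
            all(dim(exprs) == dim(calls)),
            length(conditions) == ncol(exprs))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs, calls = calls),
    colData = S4Vectors::DataFrame(condition = as.character(conditions),
                                   row.names = colnames(exprs)))
  new("ExpressionBundle", se)
}

#' SamResult: two-class SAM statistics with permutation FDR
#'
#' Holds the moderated difference statistic d_i = (mean difference) /
#' (s_i + s0), the fudge factor s0, per-gene q-values estimated by label
#' permutation, and the significant set at the working FDR threshold.
#'
#' @slot d named per-gene SAM statistic
#' @slot s0 fudge factor, expression units
#' @slot q named per-gene estimated FDR (q-value)
#' @slot significant gene IDs with q below the threshold
#' @slot fdrThreshold working FDR threshold
#' @slot nPerm number of label permutations used
#' @slot seed RNG seed used for permutation sampling
#' @export
setClass("SamResult",
  representation(d = "numeric", s0 = "numeric", q = "numeric",
                 significant = "character", fdrThreshold = "numeric",
                 nPerm = "integer", seed = "integer")
)

setValidity("SamResult", function(object) {
  msg <- character()
  if (any(object@q < 0 | object@q > 1))
    msg <- c(msg, "q-values must lie in [0, 1]")
  if (!identical(names(object@d), names(object@q)))
    msg <- c(msg, "d and q must be named identically")
  expected <- names(object@q)[object@q < object@fdrThreshold]
  if (!setequal(object@significant, expected))
    msg <- c(msg, "significant must equal the genes with q below threshold")
  if (length(msg)) msg else TRUE
})

#' StressDESets: per-stress and stress-specific differential-expression sets
#'
#' @slot de named list, stress -> DE gene IDs
#' @slot specific named list, stress -> genes DE under that stress only
#' @slot directionGroups named list mapping direction labels (e.g.
#'   elongating / shortening / neutral) to stress names
#' @slot directionSpecific named list, direction -> genes DE under every
#'   stress of that direction group and under no stress outside it
#' @export
setClass("StressDESets",
  representation(de = "list", specific = "list",
                 directionGroups = "list", directionSpecific = "list")
)

setValidity("StressDESets", function(object) {
  msg <- character()
  if (!identical(sort(names(object@de)), sort(names(object@specific))))
    msg <- c(msg, "de and specific must cover the same stresses")
  for (s in names(object@specific)) {
    if (!all(object@specific[[s]] %in% object@de[[s]]))
      msg <- c(msg, sprintf("specific[%s] must be a subset of de[%s]", s, s))
    for (t in setdiff(names(object@de), s)) {
      if (length(intersect(object@specific[[s]], object@de[[t]])))
        msg <- c(msg, sprintf("specific[%s] intersects de[%s]", s, t))
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Network
## ---------------------------------------------------------------------------

#' GeneNetwork: an undirected gene network with TLM and DE annotations
#'
#' Wraps a simple undirected igraph graph over gene IDs, together with the
#' set of telomere length maintenance (TLM) genes and per-stress
#' differentially-expressed gene flags used by the proximity test.
#'
#' @slot graph an `igraph` object; simple (no self-loops, no multi-edges)
#' @slot tlm character vector of TLM gene IDs (nodes of the graph)
#' @slot deByStress named list, stress -> DE gene IDs (nodes of the graph)
#' @export
setClass("GeneNetwork",
  representation(graph = "ANY", tlm = "character", deByStress = "list")
)

setValidity("GeneNetwork", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@graph))
    return("graph must be an igraph object")
  g <- object@graph
  if (igraph::is_directed(g))
    msg <- c(msg, "graph must be undirected")
  if (!igraph::is_simple(g))
    msg <- c(msg, "graph must be simple (no self-loops or duplicate edges)")
  nodes <- igraph::V(g)$name
  if (is.null(nodes))
    return("graph vertices must be named with gene IDs")
  if (!all(object@tlm %in% nodes))
    msg <- c(msg, "all TLM flags must name existing nodes")
  for (s in names(object@deByStress))
    if (!all(object@deByStress[[s]] %in% nodes))
      msg <- c(msg, sprintf("DE flags for '%s' name absent nodes", s))
  if (length(msg)) msg else TRUE
})

#' Construct a GeneNetwork
#'
#' @param graph an undirected `igraph` with named vertices (multi-edges and
#'   self-loops are collapsed)
#' @param tlm character vector of TLM gene IDs
#' @param deByStress named list of per-stress DE gene ID vectors
#' @return a [GeneNetwork-class]
#' @export
GeneNetwork <- function(graph, tlm = character(), deByStress = list()) {
  graph <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  new("GeneNetwork", graph = graph, tlm = as.character(tlm),
      deByStress = deByStress)
}

#' ProximityResult: a network-proximity rank-sum comparison
#'
#' @slot distA pairwise shortest-path lengths within the focal gene set
#' @slot distB pairwise shortest-path lengths within the background set
#' @slot statistic Mann-Whitney U statistic for set A
#' @slot p p-value under the stated alternative
#' @slot alternative the tested alternative hypothesis
#' @slot nExcludedPairs unreachable (cross-component) pairs excluded
#' @slot comparison human-readable label of what was compared
#' @export
setClass("ProximityResult",
  representation(distA = "numeric", distB = "numeric", statistic = "numeric",
                 p = "numeric", alternative = "character",
                 nExcludedPairs = "integer", comparison = "character")
)

setValidity("ProximityResult", function(object) {
  msg <- character()
  if (object@p < 0 || object@p > 1)
    msg <- c(msg, "p must lie in [0, 1]")
  if (any(c(object@distA, object@distB) <= 0) ||
      any(c(object@distA, object@distB) %% 1 != 0))
    msg <- c(msg, "distances must be positive integers")
  if (object@nExcludedPairs < 0)
    msg <- c(msg, "nExcludedPairs must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Screen
## ---------------------------------------------------------------------------

#' RegressionFit: robust linear fit of length change on initial length
#'
#' Result of iteratively reweighted least squares with Tukey bisquare
#' weights, modelling delta = slope * initial + intercept.
#'
#' @slot slope bp change per bp of initial length
#' @slot intercept bp
#' @slot scale robust residual SD (1.4826 x MAD of residuals), bp
#' @slot weights final bisquare weights, in [0, 1]
#' @slot residuals delta - (slope * initial + intercept), bp
#' @slot converged whether IRLS reached the coefficient tolerance
#' @slot nIter iterations used
#' @export
setClass("RegressionFit",
  representation(slope = "numeric", intercept = "numeric", scale = "numeric",
                 weights = "numeric", residuals = "numeric",
                 converged = "logical", nIter = "integer")
)

setValidity("RegressionFit", function(object) {
  msg <- character()
  if (any(object@weights < 0 | object@weights > 1))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (length(object@weights) != length(object@residuals))
    msg <- c(msg, "weights and residuals must have equal length")
  if (object@scale < 0) msg <- c(msg, "scale must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ChIP
## ---------------------------------------------------------------------------

#' EnrichmentResult: replicate-summarized ChIP fold enrichment
#'
#' @slot fold geometric-mean fold enrichment across replicates
#' @slot log2Fold log2 of `fold`
#' @slot spread SD of per-replicate log2 folds
#' @slot nReplicates number of replicates summarized
#' @slot condition condition label
#' @export
setClass("EnrichmentResult",
  representation(fold = "numeric", log2Fold = "numeric", spread = "numeric",
                 nReplicates = "integer", condition = "character")
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (object@fold <= 0) msg <- c(msg, "fold must be positive")
  if (abs(object@log2Fold - log2(object@fold)) > 1e-8)
    msg <- c(msg, "log2Fold must equal log2(fold)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic ground truth
## ---------------------------------------------------------------------------

#' SyntheticTruth: ground truth carried alongside generated data
#'
#' Every generator returns one of these so parameter-recovery tests can
#' compare estimates against what was planted.
#'
#' @slot deGenes named list, stress -> planted DE gene IDs
#' @slot plantedProximal gene IDs planted as a mutually proximal network set
#' @slot screenOutliers named list, stress -> planted outlier mutant IDs
#' @slot trueSlope named numeric, stress -> planted screen slope
#' @slot trueIntercept named numeric, stress -> planted screen intercept (bp)
#' @slot trueFragmentSizes named numeric, lane -> true fragment size (bp)
#' @slot seed RNG seed used by the generator
#' @export
setClass("SyntheticTruth",
  representation(deGenes = "list", plantedProximal = "character",
                 screenOutliers = "list", trueSlope = "numeric",
                 trueIntercept = "numeric", trueFragmentSizes = "numeric",
                 seed = "integer")
)

SyntheticTruth <- function(deGenes = list(), plantedProximal = character(),
                           screenOutliers = list(), trueSlope = numeric(),
                           trueIntercept = numeric(),
                           trueFragmentSizes = numeric(), seed = NA_integer_) {
  new("SyntheticTruth", deGenes = deGenes,
      plantedProximal = plantedProximal, screenOutliers = screenOutliers,
      trueSlope = trueSlope, trueIntercept = trueIntercept,
      trueFragmentSizes = trueFragmentSizes, seed = as.integer(seed))
}
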