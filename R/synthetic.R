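## Synthetic-data generators. Every pipeline input can be generated with
## known ground truth, emulating the statistical structure the analyses
## assume: planted DE genes on a 4-control / 3-stress array design,
## a stochastic-block-model network with a planted proximal TLM set,
## screen tables with a linear initial-length/response relation plus
## planted outliers, lane profiles from the log-linear migration model,
## and ChIP quantification quadruples around a true fold.

.checkCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x %% 1 != 0)
    stop(sprintf("'%s' must be a positive integer (got %s)", name,
                 paste(x, collapse = ",")))
  as.integer(x)
}

#' Generate a synthetic expression bundle with planted DE genes
#'
#' Emulates a normalized (log-scale) microarray experiment: `nControl`
#' wild-type samples plus `nStress` samples per stress, i.i.d. Gaussian
#' noise around per-gene baselines, and, per stress, exactly
#' `round(deFraction * nGenes)` planted genes whose mean is shifted by
#' `effect` (sign drawn per gene) in that stress's samples only. Detection
#' calls are drawn independently of DE status: 'A' with probability
#' `absentRate`, the rest 'P' or (rarely) 'M'.
#'
#' @param nGenes number of genes (>= 50)
#' @param nControl control (wild-type) samples; the published design uses 4
#' @param nStress samples per stress; the published design uses 3
#' @param stresses character vector of stress labels
#' @param deFraction fraction of genes planted as DE per stress, in [0, 1)
#' @param effect absolute log2 mean shift of planted genes
#' @param sigma noise SD on the normalized scale
#' @param absentRate probability a detection call is 'A'
#' @param seed RNG seed; same seed gives identical output
#' @return list with `bundle` (an [ExpressionBundle-class]) and `truth`
#'   (a [SyntheticTruth-class])
#' @examples
#' sim <- genExpression(nGenes = 100, deFraction = 0.1, seed = 1)
#' sim$bundle
#' @export
genExpression <- function(nGenes = 1000, nControl = 4, nStress = 3,
                          stresses = c("ethanol", "caffeine",
                                       "high_temperature", "H2O2"),
                          deFraction = 0.05, effect = 0.75, sigma = 0.25,
                          absentRate = 0.1, seed = 1) {
  nGenes <- .checkCount(nGenes, "nGenes")
  nControl <- .checkCount(nControl, "nControl")
  nStress <- .checkCount(nStress, "nStress")
  if (nGenes < 50) stop("'nGenes' must be at least 50")
  if (deFraction < 0 || deFraction >= 1)
    stop("'deFraction' must lie in [0, 1)")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (absentRate < 0 || absentRate >= 1)
    stop("'absentRate' must lie in [0, 1)")
  stresses <- as.character(stresses)

  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(nGenes))
    samples <- c(paste0("control_", seq_len(nControl)),
                 unlist(lapply(stresses,
                               function(s) paste0(s, "_", seq_len(nStress)))))
    conditions <- c(rep("control", nControl),
                    rep(stresses, each = nStress))
    baseline <- rnorm(nGenes, mean = 7, sd = 1)
    mat <- matrix(rnorm(nGenes * length(samples), mean = baseline,
                        sd = sigma),
                  nrow = nGenes, ncol = length(samples),
                  dimnames = list(genes, samples))
    nDe <- round(deFraction * nGenes)
    deGenes <- list()
    for (s in stresses) {
      idx <- if (nDe > 0) sort(sample.int(nGenes, nDe)) else integer()
      signs <- if (nDe > 0) sample(c(-1, 1), nDe, replace = TRUE) else numeric()
      cols <- which(conditions == s)
      mat[idx, cols] <- mat[idx, cols] + signs * effect
      deGenes[[s]] <- genes[idx]
    }
    u <- runif(nGenes * length(samples))
    calls <- matrix(ifelse(u < absentRate, "A",
                           ifelse(u < absentRate + 0.05 * (1 - absentRate),
                                  "M", "P")),
                    nrow = nGenes, dimnames = dimnames(mat))
    list(bundle = ExpressionBundle(mat, calls, conditions),
         truth = SyntheticTruth(deGenes = deGenes, seed = seed))
  })
}

#' Generate a block-model gene network with a planted proximal TLM set
#'
#' Draws a stochastic block model (equal-sized blocks, within-block edge
#' probability `pIn`, between-block `pOut`). When `planted = TRUE`, a set of
#' `plantedSize` TLM-flagged, DE-flagged nodes is placed inside a single
#' block, making its members mutually proximal; the remaining TLM genes are
#' scattered over the other blocks. When `planted = FALSE`, TLM and DE flags
#' are assigned uniformly at random, independent of block structure.
#' `deNonTlm` scattered non-TLM nodes are additionally DE-flagged so the
#' specificity control has a background set.
#'
#' @param nNodes total nodes
#' @param nBlocks number of blocks
#' @param pIn within-block edge probability; must exceed `pOut`
#' @param pOut between-block edge probability
#' @param tlmFraction fraction of nodes flagged as TLM genes
#' @param planted place the DE-TLM set inside one block?
#' @param plantedSize size of the DE-TLM set
#' @param deNonTlm number of scattered DE non-TLM nodes
#' @param stress stress label attached to the DE flags
#' @param seed RNG seed
#' @param nodeNames optional explicit node IDs (length `nNodes`)
#' @param plantedNodes optional explicit IDs (among `nodeNames`) to use as
#'   the planted set; they are placed in the first block
#' @param deNonTlmNodes optional explicit IDs for the DE non-TLM flags
#' @return list with `network` (a [GeneNetwork-class]) and `truth`
#'   (a [SyntheticTruth-class])
#' @export
genNetwork <- function(nNodes = 300, nBlocks = 6, pIn = 0.3, pOut = 0.01,
                       tlmFraction = 0.15, planted = TRUE, plantedSize = 15,
                       deNonTlm = plantedSize, stress = "ethanol", seed = 1,
                       nodeNames = NULL, plantedNodes = NULL,
                       deNonTlmNodes = NULL) {
  nNodes <- .checkCount(nNodes, "nNodes")
  nBlocks <- .checkCount(nBlocks, "nBlocks")
  plantedSize <- .checkCount(plantedSize, "plantedSize")
  if (pIn <= pOut)
    stop("'pIn' must exceed 'pOut': planted proximity would be undefined")
  sizes <- rep(nNodes %/% nBlocks, nBlocks)
  sizes[seq_len(nNodes %% nBlocks)] <- sizes[seq_len(nNodes %% nBlocks)] + 1L
  if (planted && plantedSize > max(sizes))
    stop("'plantedSize' exceeds the largest block size")
  nTlm <- round(tlmFraction * nNodes)
  if (nTlm < plantedSize && planted)
    stop("'tlmFraction' too small to hold the planted set")

  withr::with_seed(seed, {
    if (is.null(nodeNames)) nodeNames <- sprintf("n%04d", seq_len(nNodes))
    stopifnot(length(nodeNames) == nNodes, !anyDuplicated(nodeNames))
    pref <- matrix(pOut, nBlocks, nBlocks)
    diag(pref) <- pIn
    g <- igraph::sample_sbm(nNodes, pref.matrix = pref, block.sizes = sizes)
    block <- rep(seq_len(nBlocks), sizes)

    if (!is.null(plantedNodes)) {
      # place the requested IDs in block 1 by permuting names
      stopifnot(all(plantedNodes %in% nodeNames),
                length(plantedNodes) <= sizes[1])
      rest <- setdiff(nodeNames, plantedNodes)
      nodeNames <- c(plantedNodes, sample(rest))
    }
    igraph::V(g)$name <- nodeNames

    if (planted) {
      blockOne <- nodeNames[block == 1L]
      plantedSet <- if (!is.null(plantedNodes)) plantedNodes
                    else sample(blockOne, plantedSize)
      otherTlm <- sample(setdiff(nodeNames, c(blockOne, deNonTlmNodes)),
                         nTlm - plantedSize)
      tlm <- c(plantedSet, otherTlm)
      deTlm <- plantedSet
    } else {
      tlm <- sample(setdiff(nodeNames, deNonTlmNodes), nTlm)
      plantedSet <- character()
      deTlm <- sample(tlm, min(plantedSize, nTlm))
    }
    nonTlm <- setdiff(nodeNames, tlm)
    deOther <- if (!is.null(deNonTlmNodes)) {
      stopifnot(all(deNonTlmNodes %in% nonTlm))
      deNonTlmNodes
    } else sample(nonTlm, min(deNonTlm, length(nonTlm)))
    net <- GeneNetwork(g, tlm = tlm,
                       deByStress = stats::setNames(
                         list(c(deTlm, deOther)), stress))
    list(network = net,
         truth = SyntheticTruth(plantedProximal = plantedSet, seed = seed))
  })
}

#' Generate a mutant screen table with a linear response and planted outliers
#'
#' Initial telomeric-repeat lengths are drawn uniformly on `initialRange`
#' (the wild type carries ~350 bp of repeats; the range brackets the short
#' and long mutants). The length change after 100 generations follows
#' `delta = slope * initial + intercept + N(0, sigma^2)`; a fraction of
#' mutants is shifted by `outlierShift` bp, with the shift's sign drawn by a
#' fair coin per outlier. An `outlierShift` of at least 4 sigma is
#' recommended for recoverability.
#'
#' @param nMutants number of mutants
#' @param slope planted slope (bp change per bp of initial length)
#' @param intercept planted intercept (bp)
#' @param sigma residual SD (bp); must be positive
#' @param outlierFraction fraction of mutants planted as outliers
#' @param outlierShift absolute residual shift of planted outliers (bp)
#' @param initialRange range of initial repeat lengths (bp)
#' @param stress stress label for the table
#' @param seed RNG seed
#' @return list with `table` (data.frame: mutant, initial, final, delta,
#'   stress) and `truth` (a [SyntheticTruth-class])
#' @export
genScreen <- function(nMutants = 100, slope = -0.8, intercept = 40,
                      sigma = 10, outlierFraction = 0.05, outlierShift = 80,
                      initialRange = c(150, 450), stress = "ethanol",
                      seed = 1) {
  nMutants <- .checkCount(nMutants, "nMutants")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (outlierFraction < 0 || outlierFraction >= 1)
    stop("'outlierFraction' must lie in [0, 1)")
  withr::with_seed(seed, {
    mutant <- sprintf("m%03d", seq_len(nMutants))
    initial <- runif(nMutants, initialRange[1], initialRange[2])
    delta <- slope * initial + intercept + rnorm(nMutants, 0, sigma)
    nOut <- round(outlierFraction * nMutants)
    outIdx <- if (nOut > 0) sort(sample.int(nMutants, nOut)) else integer()
    if (nOut > 0) {
      shiftSign <- sample(c(-1, 1), nOut, replace = TRUE)
      delta[outIdx] <- delta[outIdx] + shiftSign * outlierShift
    }
    tab <- data.frame(mutant = mutant, initial = initial,
                      final = initial + delta, delta = delta,
                      stress = stress, stringsAsFactors = FALSE)
    truth <- SyntheticTruth(
      screenOutliers = stats::setNames(list(mutant[outIdx]), stress),
      trueSlope = stats::setNames(slope, stress),
      trueIntercept = stats::setNames(intercept, stress),
      seed = seed)
    list(table = tab, truth = truth)
  })
}

#' Generate a lane densitometry profile from the log-linear migration model
#'
#' Forward model for the lane quantifier: a Gaussian-shaped band centered at
#' the migration position the log-linear calibration assigns to `trueSize`,
#' sitting on a flat baseline with additive Gaussian noise (clipped at
#' zero). `trueSize` must lie within the size range spanned by the markers —
#' extrapolated sizes are rejected.
#'
#' @param trueSize true fragment size (bp)
#' @param smearSd band SD in migration units
#' @param markerPositions migration coordinates of the two markers
#' @param markerSizes sizes of the two markers (bp); defaults to the
#'   2044/779 bp marker pair
#' @param baseline flat background intensity
#' @param noiseSd SD of additive intensity noise
#' @param peakHeight band amplitude above baseline
#' @param positionStep sampling step along the migration axis
#' @param seed RNG seed
#' @return a [LaneProfile-class]
#' @export
genLane <- function(trueSize, smearSd = 2, markerPositions = c(10, 50),
                    markerSizes = c(2044, 779), baseline = 5, noiseSd = 0,
                    peakHeight = 100, positionStep = 0.1, seed = 1) {
  if (trueSize < min(markerSizes) || trueSize > max(markerSizes))
    stop(sprintf(
      "'trueSize' (%g bp) must lie within the marker range [%g, %g] bp",
      trueSize, min(markerSizes), max(markerSizes)))
  calib <- calibrateSizes(markerPositions, markerSizes)
  center <- positionOf(calib, trueSize)
  span <- abs(diff(markerPositions))
  pos <- seq(min(markerPositions) - 0.2 * span,
             max(markerPositions) + 0.2 * span, by = positionStep)
  withr::with_seed(seed, {
    y <- baseline + peakHeight * exp(-(pos - center)^2 / (2 * smearSd^2))
    if (noiseSd > 0) y <- y + rnorm(length(pos), 0, noiseSd)
    LaneProfile(pos, pmax(y, 0), markerPositions, markerSizes)
  })
}

#' Generate ChIP quantification quadruples around a true fold enrichment
#'
#' Each replicate is a (telIP, ARO1IP, tel input, ARO1 input) quadruple with
#' independent log-normal measurement noise, constructed so the fold
#' enrichment [telIP/ARO1IP] / [tel input/ARO1 input] has geometric mean
#' `trueFold`.
#'
#' @param trueFold true fold enrichment
#' @param nReplicates number of replicates
#' @param cv log-scale coefficient of variation of each quantity
#' @param condition condition label
#' @param seed RNG seed
#' @return data.frame: condition, replicate, tel_ip, aro_ip, tel_input,
#'   aro_input
#' @export
genChip <- function(trueFold = 1, nReplicates = 3, cv = 0.1,
                    condition = "control", seed = 1) {
  nReplicates <- .checkCount(nReplicates, "nReplicates")
  if (trueFold <= 0) stop("'trueFold' must be positive")
  withr::with_seed(seed, {
    aroIp <- exp(rnorm(nReplicates, log(10), cv))
    telInput <- exp(rnorm(nReplicates, log(20), cv))
    aroInput <- exp(rnorm(nReplicates, log(20), cv))
    telIp <- trueFold * aroIp * telInput / aroInput *
      exp(rnorm(nReplicates, 0, cv))
    data.frame(condition = condition, replicate = seq_len(nReplicates),
               tel_ip = telIp, aro_ip = aroIp, tel_input = telInput,
               aro_input = aroInput, stringsAsFactors = FALSE)
  })
}
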