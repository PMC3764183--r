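## Differential expression extraction: detection-call filtering, the SAM
## moderated difference statistic, permutation-based FDR estimation, and
## stress-specific set construction.

#' Filter genes with a majority of absent detection calls
#'
#' Removes genes whose detection call is 'A' in more than half of the
#' samples; 'M' (marginal) counts as present. Gene order is otherwise
#' preserved, and the operation is idempotent.
#'
#' @param bundle an [ExpressionBundle-class]
#' @return the filtered [ExpressionBundle-class]
#' @export
filterAbsent <- function(bundle) {
  stopifnot(is(bundle, "ExpressionBundle"))
  calls <- detectionCalls(bundle)
  nAbsent <- rowSums(calls == "A")
  keep <- nAbsent <= ncol(calls) / 2
  if (!any(keep))
    warning("all genes removed by the absent-call filter")
  bundle[keep, ]
}

.pooledSe <- function(mat, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(diff = m2 - m1, s = s)
}

#' The SAM moderated difference statistic
#'
#' Computes d_i = (mean_stress - mean_control) / (s_i + s0), where s_i is
#' the pooled standard error of the mean difference. With s0 = 0 this is
#' exactly the ordinary two-sample pooled-variance t statistic.
#'
#' @param mat expression matrix, genes x samples
#' @param groups two-level factor of sample labels; the first level is the
#'   control (subtrahend)
#' @param s0 fudge factor (expression units), >= 0
#' @return named per-gene statistic
#' @export
samStatistic <- function(mat, groups, s0 = 0) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly two levels")
  if (any(table(groups) < 2))
    stop("each group needs at least 2 samples")
  if (s0 < 0) stop("'s0' must be non-negative")
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  ps <- .pooledSe(mat, i1, i2)
  if (s0 == 0 && any(ps$s == 0))
    stop("zero-variance gene with s0 = 0: statistic undefined; use s0 > 0")
  stats::setNames(ps$diff / (ps$s + s0), rownames(mat))
}

#' Tune the SAM fudge factor s0
#'
#' Scans candidate s0 values over the percentiles (0, 5, ..., 100) of the
#' per-gene pooled standard errors s_i and picks the one minimizing the
#' coefficient of variation of the d statistic's median absolute deviation
#' across s_i-quantile bins — the value that makes the spread of d least
#' dependent on s_i.
#'
#' @param mat expression matrix, genes x samples (>= 100 genes recommended)
#' @param groups two-level factor of sample labels
#' @param nBins number of s_i-quantile bins
#' @return the chosen s0 (expression units)
#' @export
chooseS0 <- function(mat, groups, nBins = 100) {
  groups <- as.factor(groups)
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  ps <- .pooledSe(mat, i1, i2)
  s <- ps$s
  if (max(s) - min(s) < .Machine$double.eps * max(1, max(s))) {
    warning("all s_i equal; s0 = 0")
    return(0)
  }
  nBins <- max(2L, min(nBins, floor(length(s) / 5)))
  bin <- cut(rank(s, ties.method = "first"), breaks = nBins, labels = FALSE)
  candidates <- as.numeric(quantile(s, seq(0, 1, by = 0.05)))
  cv <- vapply(candidates, function(s0) {
    d <- ps$diff / (s + s0)
    v <- vapply(split(d, bin), mad, numeric(1))
    v <- v[is.finite(v)]
    if (mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  candidates[which.min(cv)]
}

## number of elements of sortedAsc that are >= each cutoff
.countAtLeast <- function(cutoffs, sortedAsc) {
  length(sortedAsc) -
    findInterval(cutoffs, sortedAsc, left.open = TRUE)
}

#' Two-class SAM with permutation-estimated FDR
#'
#' Runs the full SAM procedure for one stress against the control samples
#' of an [ExpressionBundle-class]: tunes s0 (unless supplied), computes the
#' observed d statistics, and estimates a per-gene q-value by permuting the
#' sample labels. For the |d| cutoff that admits gene i, the estimated FDR
#' is the median (over permutations) count of permuted |d| values at or
#' above the cutoff, divided by the number of genes admitted; q is then
#' forced monotone non-increasing in |d|. All distinct label assignments are
#' enumerated when there are at most `nPerm` of them (with 4 vs 3 samples
#' there are only 35), otherwise `nPerm` assignments are sampled under
#' `seed`. Genes tied in |d| with the cutoff are all admitted.
#'
#' @param bundle an [ExpressionBundle-class] (already detection-filtered)
#' @param stress stress condition label to test
#' @param control control condition label
#' @param nPerm maximum number of permutations (>= 100)
#' @param fdrThreshold working FDR threshold; the published screen used 0.01
#' @param seed RNG seed for permutation sampling
#' @param s0 optional fudge factor; tuned via [chooseS0()] when `NULL`
#' @param fpSummary how the per-permutation false-call counts are
#'   summarized: the SAM-convention `"median"` (default) or the more
#'   conservative 90th percentile (`"q90"`)
#' @return a [SamResult-class]
#' @examples
#' sim <- genExpression(nGenes = 200, deFraction = 0.1, seed = 7)
#' res <- samFdr(filterAbsent(sim$bundle), "ethanol", nPerm = 100, seed = 7)
#' res
#' @export
samFdr <- function(bundle, stress, control = "control", nPerm = 1000,
                   fdrThreshold = 0.01, seed = 1, s0 = NULL,
                   fpSummary = c("median", "q90")) {
  fpSummary <- match.arg(fpSummary)
  stopifnot(is(bundle, "ExpressionBundle"))
  if (nPerm < 100) stop("'nPerm' must be at least 100")
  cond <- sampleConditions(bundle)
  keep <- cond %in% c(control, stress)
  if (!any(cond == control) || !any(cond == stress))
    stop("bundle lacks samples for '", control, "' or '", stress, "'")
  mat <- exprsMatrix(bundle)[, keep, drop = FALSE]
  groups <- factor(cond[keep], levels = c(control, stress))
  if (is.null(s0)) s0 <- chooseS0(mat, groups)
  d <- samStatistic(mat, groups, s0 = s0)

  n <- ncol(mat)
  n1 <- sum(groups == control)
  allPerms <- choose(n, n1)
  if (allPerms <= nPerm) {
    permSets <- combn(n, n1, simplify = FALSE)
  } else {
    permSets <- withr::with_seed(seed, replicate(
      nPerm, sort(sample.int(n, n1)), simplify = FALSE))
  }
  nPermUsed <- length(permSets)

  absD <- abs(d)
  ord <- order(absD, decreasing = TRUE)
  cutoffs <- absD[ord]
  sortedObs <- sort(absD)
  obsCount <- .countAtLeast(cutoffs, sortedObs)

  fp <- vapply(permSets, function(ctrlIdx) {
    pg <- factor(ifelse(seq_len(n) %in% ctrlIdx, control, stress),
                 levels = c(control, stress))
    dStar <- samStatistic(mat, pg, s0 = s0)
    .countAtLeast(cutoffs, sort(abs(dStar)))
  }, numeric(length(cutoffs)))
  medianFp <- if (fpSummary == "median") apply(fp, 1, median)
              else apply(fp, 1, quantile, probs = 0.9)

  q <- pmin(medianFp / obsCount, 1)
  q <- rev(cummin(rev(q)))              # monotone non-increasing in |d|
  qByGene <- numeric(length(d))
  qByGene[ord] <- q
  names(qByGene) <- names(d)
  significant <- names(qByGene)[qByGene < fdrThreshold]

  new("SamResult", d = d, s0 = s0, q = qByGene,
      significant = significant, fdrThreshold = fdrThreshold,
      nPerm = as.integer(nPermUsed), seed = as.integer(seed))
}

#' Build stress-specific and direction-specific DE gene sets
#'
#' The stress-specific set for stress s is `de[[s]]` minus every other
#' stress's DE set (the Venn region unique to s). When direction groups are
#' given (e.g. elongating = ethanol; shortening = caffeine, 37C; neutral =
#' H2O2), the direction-specific set for a group holds the genes DE under
#' every stress of that group and under no stress outside it.
#'
#' @param de named list, stress -> DE gene IDs (>= 2 stresses)
#' @param directionGroups optional named list mapping direction labels to
#'   stress names; every stress named must be present in `de`
#' @return a [StressDESets-class]
#' @examples
#' stressSpecificSets(list(ethanol = c("g1", "g2"), caffeine = c("g2", "g3")))
#' @export
stressSpecificSets <- function(de, directionGroups = list()) {
  if (length(de) < 2) stop("at least two stresses are required")
  if (is.null(names(de)) || any(names(de) == ""))
    stop("'de' must be a named list")
  unknown <- setdiff(unlist(directionGroups), names(de))
  if (length(unknown))
    stop("direction groups name unknown stresses: ",
         paste(unknown, collapse = ", "))
  specific <- lapply(names(de), function(s)
    setdiff(de[[s]], unique(unlist(de[setdiff(names(de), s)]))))
  names(specific) <- names(de)
  directionSpecific <- lapply(directionGroups, function(members) {
    inside <- Reduce(intersect, de[members])
    outside <- unique(unlist(de[setdiff(names(de), members)]))
    setdiff(inside, outside)
  })
  new("StressDESets", de = de, specific = specific,
      directionGroups = directionGroups,
      directionSpecific = directionSpecific)
}
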