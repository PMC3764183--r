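## Network proximity of stress-specific differentially expressed TLM genes:
## pairwise unweighted shortest-path distances compared between a focal set
## and a background set with a one-sided Wilcoxon rank-sum test.

#' Load a gene network with TLM and DE annotations from files
#'
#' Reads a two-column edge list (tab- or whitespace-separated, `#` comment
#' lines allowed), an optional one-ID-per-line TLM gene list, and optional
#' DE sets. Duplicate edges are collapsed (with a message), and annotation
#' IDs absent from the graph are dropped with a warning.
#'
#' @param edgeFile path to the edge list
#' @param tlmFile optional path to the TLM gene list
#' @param deSets optional [StressDESets-class] (its stress-specific sets are
#'   attached) or a plain named list of stress -> gene IDs
#' @return a [GeneNetwork-class]
#' @export
loadNetwork <- function(edgeFile, tlmFile = NULL, deSets = NULL) {
  lines <- readLines(edgeFile)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad)) {
    lineNo <- which(keep)[bad[1]]
    stop(sprintf("malformed edge line %d in '%s': need two gene IDs",
                 lineNo, edgeFile))
  }
  edges <- t(vapply(fields, function(f) f[1:2], character(2)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  nDup <- igraph::ecount(g) - igraph::ecount(igraph::simplify(g))
  if (nDup > 0)
    message(nDup, " duplicate/self-loop edge(s) collapsed")
  g <- igraph::simplify(g)
  nodes <- igraph::V(g)$name

  tlm <- character()
  if (!is.null(tlmFile)) {
    tlm <- trimws(readLines(tlmFile))
    tlm <- tlm[nzchar(tlm) & !startsWith(tlm, "#")]
    missing <- setdiff(tlm, nodes)
    if (length(missing)) {
      warning(length(missing), " TLM gene(s) absent from the graph dropped: ",
              paste(head(missing, 5), collapse = ", "))
      tlm <- intersect(tlm, nodes)
    }
  }
  deByStress <- list()
  if (!is.null(deSets)) {
    deByStress <- if (is(deSets, "StressDESets")) specificSets(deSets)
                  else deSets
    deByStress <- lapply(deByStress, function(ids) {
      missing <- setdiff(ids, nodes)
      if (length(missing))
        warning(length(missing), " DE gene(s) absent from the graph dropped")
      intersect(ids, nodes)
    })
  }
  GeneNetwork(g, tlm = tlm, deByStress = deByStress)
}

#' Pairwise unweighted shortest-path distances within a gene set
#'
#' Breadth-first shortest-path length for every unordered pair of the set.
#' Pairs in different components (unreachable) are excluded from the
#' returned multiset and counted in the `"nExcluded"` attribute rather than
#' imputed: an unweighted distance is undefined across components, and
#' imputing (e.g. diameter + 1) would manufacture proximity signal.
#'
#' @param net a [GeneNetwork-class]
#' @param geneSet at least two node IDs
#' @return numeric vector of path lengths (positive integers) with
#'   attribute `"nExcluded"`, the number of unreachable pairs
#' @export
pairwiseDistances <- function(net, geneSet) {
  stopifnot(is(net, "GeneNetwork"))
  geneSet <- unique(as.character(geneSet))
  if (length(geneSet) < 2)
    stop("'geneSet' needs at least 2 genes (got ", length(geneSet), ")")
  nodes <- igraph::V(net@graph)$name
  if (!all(geneSet %in% nodes))
    stop("gene set members absent from the network: ",
         paste(head(setdiff(geneSet, nodes), 5), collapse = ", "))
  dm <- igraph::distances(net@graph, v = geneSet, to = geneSet)
  d <- dm[upper.tri(dm)]
  out <- d[is.finite(d)]
  attr(out, "nExcluded") <- sum(!is.finite(d))
  out
}

#' Wilcoxon rank-sum test with a small-sample exact branch
#'
#' Ranks the pooled values with average ranks for ties and reports the
#' Mann-Whitney U statistic for sample `a`. The p-value is exact — computed
#' by full enumeration of all C(nA+nB, nA) rank assignments — when
#' nA + nB <= 16 and there are no ties; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param a first value multiset (the focal set)
#' @param b second value multiset (the background)
#' @param alternative `"less"` (a stochastically smaller than b),
#'   `"greater"`, or `"two.sided"`
#' @return list with `statistic` (U), `p`, `exact` (logical branch flag)
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4), "less")$p   # 1/6
#' @export
wilcoxonRankSum <- function(a, b,
                            alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both samples must be non-empty")
  nA <- length(a); nB <- length(b); n <- nA + nB
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(statistic = u, p = 1, exact = FALSE))
  }
  mu <- nA * nB / 2
  if (!ties && n <= 16) {
    combos <- combn(n, nA)
    ranks <- rank(pooled)
    uAll <- colSums(matrix(ranks[combos], nrow = nA)) - nA * (nA + 1) / 2
    p <- switch(alternative,
      less = mean(uAll <= u),
      greater = mean(uAll >= u),
      two.sided = mean(abs(uAll - mu) >= abs(u - mu)))
    return(list(statistic = u, p = p, exact = TRUE))
  }
  tieTab <- table(pooled)
  sigma2 <- nA * nB / 12 *
    ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("degenerate rank variance; p = 1")
    return(list(statistic = u, p = 1, exact = FALSE))
  }
  sg <- sqrt(sigma2)
  p <- switch(alternative,
    less = pnorm((u - mu + 0.5) / sg),
    greater = 1 - pnorm((u - mu - 0.5) / sg),
    two.sided = {
      z <- (u - mu - sign(u - mu) * 0.5) / sg
      min(1, 2 * pnorm(-abs(z)))
    })
  list(statistic = u, p = min(max(p, 0), 1), exact = FALSE)
}

.proximityCompare <- function(distA, distB, comparison) {
  w <- wilcoxonRankSum(distA, distB, alternative = "less")
  new("ProximityResult",
      distA = as.numeric(distA), distB = as.numeric(distB),
      statistic = w$statistic, p = w$p, alternative = "less",
      nExcludedPairs = as.integer(attr(distA, "nExcluded") %||% 0L) +
        as.integer(attr(distB, "nExcluded") %||% 0L),
      comparison = comparison)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Test whether stress-specific DE TLM genes are mutually proximal
#'
#' Compares the pairwise shortest-path distances within the stress-specific
#' differentially expressed TLM genes (set A = TLM genes carrying the DE
#' flag for `stress`) against the distances among the other TLM genes, with
#' a one-sided Wilcoxon rank-sum test (alternative: A's distances are
#' smaller). The default background is the pairwise distances within
#' TLM \\ A; `"all_other_tlm_pairs"` instead uses every TLM pair not
#' entirely inside A.
#'
#' @param net a [GeneNetwork-class] with TLM and DE flags
#' @param stress stress label (must be present in the network's DE flags)
#' @param bDefinition background definition, `"other_tlm"` (default) or
#'   `"all_other_tlm_pairs"`
#' @return a [ProximityResult-class]
#' @export
proximityTest <- function(net, stress,
                          bDefinition = c("other_tlm",
                                          "all_other_tlm_pairs")) {
  stopifnot(is(net, "GeneNetwork"))
  bDefinition <- match.arg(bDefinition)
  setA <- intersect(tlmGenes(net), deGenes(net, stress))
  if (length(setA) < 2)
    stop(sprintf(
      "stress-specific DE TLM set for '%s' has %d gene(s); need >= 2",
      stress, length(setA)))
  distA <- pairwiseDistances(net, setA)
  if (bDefinition == "other_tlm") {
    setB <- setdiff(tlmGenes(net), setA)
    if (length(setB) < 2)
      stop(sprintf("background TLM set has %d gene(s); need >= 2",
                   length(setB)))
    distB <- pairwiseDistances(net, setB)
    label <- sprintf("DE-TLM(%s) pairs vs other-TLM pairs", stress)
  } else {
    allTlm <- pairwiseDistancesMatrix(net, tlmGenes(net))
    inA <- rownames(allTlm) %in% setA
    keep <- upper.tri(allTlm) & !(outer(inA, inA, `&`))
    d <- allTlm[keep]
    distB <- d[is.finite(d)]
    attr(distB, "nExcluded") <- sum(!is.finite(d))
    label <- sprintf("DE-TLM(%s) pairs vs all other TLM pairs", stress)
  }
  .proximityCompare(distA, distB, label)
}

## full distance matrix over a set (internal; used by the alternative
## background definition)
pairwiseDistancesMatrix <- function(net, geneSet) {
  igraph::distances(net@graph, v = geneSet, to = geneSet)
}

#' Specificity control: is proximity unique to TLM genes?
#'
#' Repeats the proximity comparison on a (typically larger) network, but
#' against differentially expressed genes that are not TLM genes: set A is
#' the stress-specific DE TLM genes, set B the stress-specific DE non-TLM
#' genes. A small p here only for the TLM set shows that mutual closeness
#' is not a general property of differentially expressed genes.
#'
#' @param net a [GeneNetwork-class] with TLM and DE flags
#' @param stress stress label
#' @return a [ProximityResult-class]
#' @export
specificityControl <- function(net, stress) {
  stopifnot(is(net, "GeneNetwork"))
  de <- deGenes(net, stress)
  setA <- intersect(tlmGenes(net), de)
  setB <- setdiff(de, tlmGenes(net))
  if (length(setA) < 2)
    stop(sprintf("DE TLM set for '%s' has %d gene(s); need >= 2",
                 stress, length(setA)))
  if (length(setB) < 2)
    stop(sprintf("DE non-TLM set for '%s' has %d gene(s); need >= 2",
                 stress, length(setB)))
  distA <- pairwiseDistances(net, setA)
  distB <- pairwiseDistances(net, setB)
  .proximityCompare(distA, distB,
                    sprintf("DE-TLM(%s) pairs vs DE-non-TLM pairs", stress))
}
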