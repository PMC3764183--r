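## Readers and writers for the plain-text dialects the pipeline stages
## exchange: TSV matrices with a gene-ID first column, two-column maps,
## edge lists, one-ID-per-line gene lists, GMT sets, two-column lane CSVs
## with a key-value marker sidecar, and the truth manifest.

.writeTsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write an expression bundle to its three TSV files
#'
#' @param bundle an [ExpressionBundle-class]
#' @param matrixFile,callsFile,groupsFile output paths
#' @return invisibly, the three paths
#' @export
writeExpressionBundle <- function(bundle, matrixFile, callsFile, groupsFile) {
  mat <- exprsMatrix(bundle)
  .writeTsv(data.frame(gene = rownames(mat), round(mat, 6),
                       check.names = FALSE), matrixFile)
  calls <- detectionCalls(bundle)
  .writeTsv(data.frame(gene = rownames(calls), calls, check.names = FALSE),
            callsFile)
  .writeTsv(data.frame(sample = colnames(mat),
                       condition = sampleConditions(bundle)), groupsFile)
  invisible(c(matrixFile, callsFile, groupsFile))
}

#' Read an expression bundle from its three TSV files
#'
#' @param matrixFile TSV, first column gene IDs, header row of sample IDs
#' @param callsFile same-shape TSV of P/M/A characters
#' @param groupsFile two-column TSV (sample, condition)
#' @return an [ExpressionBundle-class]
#' @export
readExpressionBundle <- function(matrixFile, callsFile, groupsFile) {
  m <- utils::read.delim(matrixFile, check.names = FALSE,
                         comment.char = "#")
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m[[1]]
  cl <- utils::read.delim(callsFile, check.names = FALSE,
                          comment.char = "#")
  calls <- as.matrix(cl[, -1, drop = FALSE])
  rownames(calls) <- cl[[1]]
  if (!identical(dim(mat), dim(calls)) ||
      !identical(rownames(mat), rownames(calls)))
    stop("matrix and calls files disagree in shape or gene order")
  groups <- utils::read.delim(groupsFile, comment.char = "#")
  idx <- match(colnames(mat), groups[[1]])
  if (anyNA(idx)) stop("groups file is missing samples: ",
                       paste(colnames(mat)[is.na(idx)], collapse = ", "))
  ExpressionBundle(mat, calls, as.character(groups[[2]][idx]))
}

#' Write / read an edge list
#'
#' @param net a [GeneNetwork-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeEdgeList <- function(net, path) {
  el <- igraph::as_edgelist(networkGraph(net))
  .writeTsv(data.frame(from = el[, 1], to = el[, 2]), path)
  invisible(path)
}

#' Write a one-ID-per-line gene list
#'
#' @param ids gene IDs
#' @param path output path
#' @return invisibly, the path
#' @export
writeGeneList <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, then the member IDs, tab-separated.
#'
#' @param sets named list of gene-ID vectors
#' @param path output path
#' @param description description field (recycled)
#' @return invisibly, the path
#' @export
writeGmt <- function(sets, path, description = "telostress") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path
#' @return named list of gene-ID vectors
#' @export
readGmt <- function(path) {
  fields <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[`, character(1), 1))
}

#' Write a lane profile as a two-column CSV plus marker sidecar
#'
#' @param profile a [LaneProfile-class]
#' @param csvFile output CSV (position, intensity; with header)
#' @param markerFile optional key-value sidecar recording the marker bands;
#'   defaults to `<csvFile>.markers`
#' @return invisibly, the CSV path
#' @export
writeLaneProfile <- function(profile, csvFile,
                             markerFile = paste0(csvFile, ".markers")) {
  utils::write.table(
    data.frame(position = positions(profile),
               intensity = round(intensities(profile), 6)),
    csvFile, sep = ",", quote = FALSE, row.names = FALSE)
  writeLines(c(
    paste0("marker_position=", paste(markerPositions(profile),
                                     collapse = ",")),
    paste0("marker_size=", paste(markerSizes(profile), collapse = ","))),
    markerFile)
  invisible(csvFile)
}

#' Read a lane profile from CSV (+ marker sidecar or explicit markers)
#'
#' @param csvFile two-column CSV (position, intensity) with header
#' @param markerPositions,markerSizes explicit marker bands; when omitted,
#'   read from the `<csvFile>.markers` sidecar
#' @return a [LaneProfile-class]
#' @export
readLaneProfile <- function(csvFile, markerPositions = NULL,
                            markerSizes = NULL) {
  df <- utils::read.csv(csvFile, comment.char = "#")
  if (is.null(markerPositions) || is.null(markerSizes)) {
    sidecar <- paste0(csvFile, ".markers")
    if (!file.exists(sidecar))
      stop("no marker sidecar '", sidecar,
           "'; supply markerPositions/markerSizes")
    kv <- .readKeyValue(sidecar)
    markerPositions <- as.numeric(strsplit(kv[["marker_position"]], ",")[[1]])
    markerSizes <- as.numeric(strsplit(kv[["marker_size"]], ",")[[1]])
  }
  LaneProfile(df[[1]], df[[2]], markerPositions, markerSizes)
}

#' Read a per-stress screen table
#'
#' @param path TSV with columns mutant, initial, final (and optionally
#'   delta, stress); `#` comment lines ignored
#' @return validated data.frame (see [checkScreenTable()])
#' @export
readScreenTable <- function(path) {
  checkScreenTable(utils::read.delim(path, comment.char = "#"))
}

#' Read a ChIP quantification table
#'
#' @param path TSV with columns condition, replicate, tel_ip, aro_ip,
#'   tel_input, aro_input (or the `_ct` variants)
#' @return data.frame
#' @export
readChipTable <- function(path) {
  utils::read.delim(path, comment.char = "#")
}

.readKeyValue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}

#' Write a SyntheticTruth manifest in plain key-value text
#'
#' @param truth a [SyntheticTruth-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeTruthManifest <- function(truth, path) {
  lines <- c(paste0("seed=", truth@seed))
  for (s in names(truth@deGenes))
    lines <- c(lines, sprintf("de_genes.%s=%s", s,
                              paste(truth@deGenes[[s]], collapse = ",")))
  if (length(truth@plantedProximal))
    lines <- c(lines, paste0("planted_proximal=",
                             paste(truth@plantedProximal, collapse = ",")))
  for (s in names(truth@screenOutliers))
    lines <- c(lines, sprintf("screen_outliers.%s=%s", s,
                              paste(truth@screenOutliers[[s]],
                                    collapse = ",")))
  for (s in names(truth@trueSlope))
    lines <- c(lines, sprintf("true_slope.%s=%g", s, truth@trueSlope[[s]]))
  for (s in names(truth@trueIntercept))
    lines <- c(lines, sprintf("true_intercept.%s=%g", s,
                              truth@trueIntercept[[s]]))
  for (s in names(truth@trueFragmentSizes))
    lines <- c(lines, sprintf("true_fragment_sizes.%s=%g", s,
                              truth@trueFragmentSizes[[s]]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SyntheticTruth manifest
#'
#' @param path manifest path written by [writeTruthManifest()]
#' @return a [SyntheticTruth-class]
#' @export
readTruthManifest <- function(path) {
  kv <- .readKeyValue(path)
  pick <- function(prefix) {
    nms <- names(kv)[startsWith(names(kv), paste0(prefix, "."))]
    stats::setNames(lapply(kv[nms], function(v) strsplit(v, ",")[[1]]),
                    sub(paste0("^", prefix, "\\."), "", nms))
  }
  num <- function(lst) vapply(lst, function(v) as.numeric(v[1]), numeric(1))
  SyntheticTruth(
    deGenes = pick("de_genes"),
    plantedProximal = if ("planted_proximal" %in% names(kv))
      strsplit(kv[["planted_proximal"]], ",")[[1]] else character(),
    screenOutliers = pick("screen_outliers"),
    trueSlope = num(pick("true_slope")),
    trueIntercept = num(pick("true_intercept")),
    trueFragmentSizes = num(pick("true_fragment_sizes")),
    seed = as.integer(kv[["seed"]]))
}
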