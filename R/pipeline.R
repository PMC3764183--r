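## End-to-end orchestration: fixture generation with a truth manifest, and
## a config-driven run of every stage in dependency order.

.fixtureStresses <- c("ethanol", "caffeine", "high_temperature", "H2O2")

.fixtureDirections <- list(elongating = "ethanol",
                           shortening = c("caffeine", "high_temperature"),
                           neutral = "H2O2")

## screen generator settings per stress: elongation in ethanol scales up
## with initial length; shortening in caffeine / 37C scales down
.fixtureScreens <- list(
  ethanol = list(slope = 0.4, intercept = -40, direction = "elongating"),
  caffeine = list(slope = -0.5, intercept = 80, direction = "shortening"),
  high_temperature = list(slope = -0.8, intercept = 150,
                          direction = "shortening"))

## lane truth: wild-type telomere ~1250 bp; elongation under ethanol,
## shortening under caffeine / 37C, no change under H2O2
.fixtureLanes <- c(control = 1250, ethanol = 1400, caffeine = 1100,
                   high_temperature = 1030, H2O2 = 1250)

#' Write a complete synthetic study directory with a truth manifest
#'
#' Generates every input the pipeline stages read — expression matrix,
#' detection calls, sample-to-condition map, network edge list, TLM gene
#' list, per-stress screen tables, lane densitometry profiles and a ChIP
#' table — plus a `truth.txt` ground-truth manifest and a ready-to-run
#' `config.yaml`. The network is built over gene IDs from the expression
#' universe, with the planted proximal set drawn from the ethanol-specific
#' planted DE genes, so the downstream stages recover a coherent story.
#'
#' @param seed integer seed controlling every generator
#' @param outDir output directory (created if needed; must be writable)
#' @return invisibly, the path to the written `config.yaml`
#' @examples
#' dir <- tempfile("fixtures")
#' cfg <- makeFixtures(seed = 1, outDir = dir)
#' @export
makeFixtures <- function(seed = 1, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", outDir, "'")
  if (file.access(outDir, mode = 2) != 0)
    stop("output directory '", outDir, "' is not writable")
  p <- function(...) file.path(outDir, ...)
  seed <- as.integer(seed)

  expr <- genExpression(nGenes = 1000, nControl = 4, nStress = 3,
                        stresses = .fixtureStresses, deFraction = 0.05,
                        effect = 0.75, sigma = 0.25, absentRate = 0.1,
                        seed = seed)
  writeExpressionBundle(expr$bundle, p("expression.tsv"), p("calls.tsv"),
                        p("groups.tsv"))
  de <- plantedDeGenes(expr$truth)

  ## network nodes come from the expression gene universe; the planted
  ## proximal set and the scattered DE non-TLM control set are both
  ## ethanol-only planted DE genes
  ethanolOnly <- setdiff(de$ethanol, unlist(de[names(de) != "ethanol"]))
  genes <- rownames(exprsMatrix(expr$bundle))
  withr::with_seed(seed + 1L, {
    plantedNodes <- sample(ethanolOnly, 15)
    deNonTlmNodes <- sample(setdiff(ethanolOnly, plantedNodes), 15)
    others <- sample(setdiff(genes, c(plantedNodes, deNonTlmNodes)),
                     300 - 30)
  })
  net <- genNetwork(nNodes = 300, nBlocks = 6, pIn = 0.3, pOut = 0.01,
                    tlmFraction = 0.15, planted = TRUE, plantedSize = 15,
                    stress = "ethanol", seed = seed + 1L,
                    nodeNames = c(plantedNodes, deNonTlmNodes, others),
                    plantedNodes = plantedNodes,
                    deNonTlmNodes = deNonTlmNodes)
  writeEdgeList(net$network, p("network_edges.tsv"))
  writeGeneList(tlmGenes(net$network), p("tlm_genes.txt"))

  screenTruths <- list()
  for (i in seq_along(.fixtureScreens)) {
    s <- names(.fixtureScreens)[i]
    cfg <- .fixtureScreens[[s]]
    scr <- genScreen(nMutants = 100, slope = cfg$slope,
                     intercept = cfg$intercept, sigma = 10,
                     outlierFraction = 0.05, outlierShift = 80,
                     stress = s, seed = seed + 1L + i)
    .writeTsv(scr$table, p(sprintf("screen_%s.tsv", s)))
    screenTruths[[s]] <- scr$truth
  }

  laneDir <- p("lanes")
  dir.create(laneDir, showWarnings = FALSE)
  for (i in seq_along(.fixtureLanes)) {
    lane <- genLane(.fixtureLanes[i], smearSd = 2, noiseSd = 1,
                    seed = seed + 10L + i)
    writeLaneProfile(lane, file.path(laneDir,
                                     sprintf("lane_%s.csv",
                                             names(.fixtureLanes)[i])))
  }

  chip <- rbind(genChip(trueFold = 2, nReplicates = 3, condition = "control",
                        seed = seed + 20L),
                genChip(trueFold = 1, nReplicates = 3, condition = "ethanol",
                        seed = seed + 21L))
  .writeTsv(chip, p("chip.tsv"))

  truth <- SyntheticTruth(
    deGenes = de,
    plantedProximal = plantedNodes,
    screenOutliers = lapply(screenTruths, function(t)
      plantedOutliers(t)[[1]]),
    trueSlope = vapply(.fixtureScreens, `[[`, numeric(1), "slope"),
    trueIntercept = vapply(.fixtureScreens, `[[`, numeric(1), "intercept"),
    trueFragmentSizes = .fixtureLanes,
    seed = seed)
  writeTruthManifest(truth, p("truth.txt"))

  config <- list(
    out_dir = file.path(outDir, "results"),
    seeds = list(de = seed + 100L),
    expression = list(matrix = p("expression.tsv"),
                      calls = p("calls.tsv"),
                      groups = p("groups.tsv"),
                      control = "control",
                      stresses = as.list(.fixtureStresses),
                      fdr_threshold = 0.01, n_perm = 1000),
    direction_groups = lapply(.fixtureDirections, as.list),
    network = list(edges = p("network_edges.tsv"),
                   tlm = p("tlm_genes.txt")),
    screen = list(
      tables = stats::setNames(
        lapply(names(.fixtureScreens),
               function(s) p(sprintf("screen_%s.tsv", s))),
        names(.fixtureScreens)),
      directions = lapply(.fixtureScreens, `[[`, "direction"),
      alpha = 0.05),
    lane_quant = list(
      lanes = stats::setNames(
        as.list(file.path(laneDir, sprintf("lane_%s.csv",
                                           names(.fixtureLanes)))),
        names(.fixtureLanes)),
      control_lane = "control",
      threshold_fraction = 0.2, background_quantile = 0.1),
    chip = list(table = p("chip.tsv"), control_condition = "control"))
  yaml::write_yaml(config, p("config.yaml"))
  invisible(p("config.yaml"))
}

.requireField <- function(config, path) {
  node <- config
  for (key in path) {
    if (!is.list(node) || is.null(node[[key]]))
      stop("config is missing required field '",
           paste(path, collapse = "."), "'")
    node <- node[[key]]
  }
  node
}

.requirePath <- function(config, path) {
  value <- .requireField(config, path)
  files <- unlist(value)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("config field '", paste(path, collapse = "."),
         "' points at missing file(s): ", paste(missing, collapse = ", "))
  value
}

#' Validate a pipeline configuration before anything runs
#'
#' Checks that every required field is present, every referenced input path
#' exists and every stochastic stage has an explicit seed; the error names
#' the offending field.
#'
#' @param config a configuration list (see [runAll()])
#' @return the validated config, invisibly
#' @export
validateConfig <- function(config) {
  .requireField(config, "out_dir")
  .requirePath(config, c("expression", "matrix"))
  .requirePath(config, c("expression", "calls"))
  .requirePath(config, c("expression", "groups"))
  .requireField(config, c("expression", "control"))
  .requireField(config, c("expression", "stresses"))
  .requireField(config, c("expression", "fdr_threshold"))
  .requireField(config, c("expression", "n_perm"))
  .requireField(config, c("seeds", "de"))
  .requirePath(config, c("network", "edges"))
  .requirePath(config, c("network", "tlm"))
  .requirePath(config, c("screen", "tables"))
  .requireField(config, c("screen", "directions"))
  .requireField(config, c("screen", "alpha"))
  .requirePath(config, c("lane_quant", "lanes"))
  .requirePath(config, c("chip", "table"))
  invisible(config)
}

.provenance <- function(stage, params, seed = NULL) {
  paste0("stage=", stage,
         if (!is.null(seed)) paste0(" seed=", seed) else "",
         " ", paste(names(params), unlist(params), sep = "=",
                    collapse = " "))
}

#' Run every pipeline stage from a configuration
#'
#' Stages run in dependency order: lane quantification, then the screen;
#' expression DE extraction, then set construction, then the network
#' proximity tests; ChIP independently. Every output table carries a
#' provenance `#` header (stage, parameters, seed), and identical
#' config + seeds give byte-identical outputs. The configuration is fully
#' validated before any stage runs. A stress whose DE-TLM set is too small
#' for the proximity test (fewer than 2 genes on the network — expected for
#' a stress that leaves telomere length alone) is recorded as untestable in
#' the results rather than failing the run.
#'
#' @param config a config list, or the path to a YAML file with the layout
#'   written by [makeFixtures()]
#' @return invisibly, a list of per-stage results (lengths table, SAM
#'   results, DE sets, proximity results, screen fits and calls, ChIP
#'   summary, paths of written artifacts)
#' @examples
#' dir <- tempfile("study")
#' cfg <- makeFixtures(seed = 1, outDir = dir)
#' res <- runAll(cfg)
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validateConfig(config)
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  o <- function(...) file.path(outDir, ...)
  report <- c("telostress pipeline report", "==========================")
  results <- list()

  ## --- lane quantification ------------------------------------------------------
  tq <- config$lane_quant
  thr <- tq$threshold_fraction %||% 0.2
  bgq <- tq$background_quantile %||% 0.1
  lanes <- unlist(tq$lanes)
  est <- lapply(lanes, function(f)
    estimateLength(readLaneProfile(f), thresholdFraction = thr,
                   backgroundQuantile = bgq))
  lengths <- data.frame(lane = names(lanes),
                        length_bp = round(vapply(est, lengthBp, numeric(1)),
                                          2),
                        smear_lo = round(vapply(est, function(e)
                          smearRange(e)[["lo"]], numeric(1)), 2),
                        smear_hi = round(vapply(est, function(e)
                          smearRange(e)[["hi"]], numeric(1)), 2))
  ctrlLane <- tq$control_lane
  if (!is.null(ctrlLane) && ctrlLane %in% names(lanes)) {
    ctrlEst <- est[[which(names(lanes) == ctrlLane)]]
    lengths$delta_bp <- round(vapply(est, deltaLength,
                                     control = ctrlEst, numeric(1)), 2)
  }
  .writeTsv(lengths, o("telomere_lengths.tsv"),
            .provenance("lane_quant", list(threshold_fraction = thr,
                                         background_quantile = bgq)))
  results$lengths <- lengths
  report <- c(report, "", "[lane quantification]",
              sprintf("  %s: %.1f bp", lengths$lane, lengths$length_bp))

  ## --- expression DE -------------------------------------------------
  ex <- config$expression
  deSeed <- as.integer(.requireField(config, c("seeds", "de")))
  bundle <- filterAbsent(readExpressionBundle(ex$matrix, ex$calls,
                                              ex$groups))
  stresses <- unlist(ex$stresses)
  sam <- lapply(stresses, function(s)
    samFdr(bundle, s, control = ex$control, nPerm = ex$n_perm,
           fdrThreshold = ex$fdr_threshold, seed = deSeed))
  names(sam) <- stresses
  de <- lapply(sam, significantGenes)
  results$sam <- sam
  deCounts <- data.frame(stress = stresses,
                         n_de = vapply(de, length, integer(1)),
                         s0 = round(vapply(sam, samS0, numeric(1)), 6),
                         n_perm = vapply(sam, function(r) r@nPerm,
                                         integer(1)))
  .writeTsv(deCounts, o("de_counts.tsv"),
            .provenance("de", list(fdr_threshold = ex$fdr_threshold),
                        deSeed))
  report <- c(report, "", sprintf("[de] seed=%d FDR<%g", deSeed,
                                  ex$fdr_threshold),
              sprintf("  %s: %d DE genes", deCounts$stress, deCounts$n_de))

  ## --- stress-specific sets ------------------------------------------
  dirGroups <- lapply(config$direction_groups %||% list(), unlist)
  sets <- stressSpecificSets(de, dirGroups)
  writeGmt(c(stats::setNames(deSets(sets), paste0("de_", stresses)),
             stats::setNames(specificSets(sets),
                             paste0("specific_", stresses))),
           o("de_sets.gmt"))
  results$sets <- sets
  report <- c(report, "", "[sets]",
              sprintf("  specific %s: %d genes", stresses,
                      vapply(specificSets(sets), length, integer(1))))

  ## --- network proximity ---------------------------------------------
  net <- loadNetwork(config$network$edges, config$network$tlm, sets)
  proxRows <- lapply(stresses, function(s) {
    setA <- intersect(tlmGenes(net), deGenes(net, s) %||% character())
    if (length(setA) < 2)
      return(data.frame(stress = s, n_a = length(setA), n_b = NA,
                        statistic = NA, p = NA, excluded_pairs = NA,
                        note = "untestable: DE-TLM set < 2"))
    pr <- proximityTest(net, s)
    results$proximity[[s]] <<- pr
    data.frame(stress = s, n_a = length(proximalDistances(pr)),
               n_b = length(backgroundDistances(pr)),
               statistic = pr@statistic, p = signif(pValue(pr), 6),
               excluded_pairs = excludedPairs(pr), note = "")
  })
  proxTab <- do.call(rbind, proxRows)
  .writeTsv(proxTab, o("proximity.tsv"),
            .provenance("proximity", list(b_definition = "other_tlm")))
  report <- c(report, "", "[proximity]",
              sprintf("  %s: p=%s %s", proxTab$stress,
                      ifelse(is.na(proxTab$p), "NA",
                             formatC(proxTab$p, digits = 3)),
                      proxTab$note))
  results$proximityTable <- proxTab

  ## --- screen ---------------------------------------------------------
  sc <- config$screen
  screenRows <- list()
  for (s in names(sc$tables)) {
    tab <- readScreenTable(sc$tables[[s]])
    fit <- robustFit(tab$initial, tab$delta)
    corr <- pearsonCorrelation(tab$initial, tab$delta)
    calls <- callOutliers(fit, alpha = sc$alpha,
                          stressDirection = sc$directions[[s]],
                          mutants = tab$mutant)
    hdr <- sprintf(
      "stage=screen stress=%s slope=%.6g intercept=%.6g scale=%.6g r=%.4f p=%.3g alpha=%g",
      s, coef(fit)[["slope"]], coef(fit)[["intercept"]], fitScale(fit),
      corr$r, corr$p, sc$alpha)
    out <- data.frame(mutant = calls$mutant,
                      initial = round(tab$initial, 2),
                      delta = round(tab$delta, 2),
                      z = round(calls$z, 4), flagged = calls$flagged,
                      direction = calls$direction)
    con <- file(o(sprintf("screen_results_%s.tsv", s)), "wt")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    results$screen[[s]] <- list(fit = fit, correlation = corr,
                                calls = calls)
    report <- c(report, "", sprintf(
      "[screen %s] slope=%.3f r=%.3f p=%.2g flagged=%d",
      s, coef(fit)[["slope"]], corr$r, corr$p, sum(calls$flagged)))
  }

  ## --- chip -----------------------------------------------------------
  chipTab <- readChipTable(config$chip$table)
  chipRes <- chipSummary(chipTab)
  ctrlCond <- config$chip$control_condition %||% "control"
  if (ctrlCond %in% chipRes$condition) {
    ctrlFold <- chipRes$fold[chipRes$condition == ctrlCond]
    chipRes$relative_change <- round(chipRes$fold / ctrlFold, 4)
  }
  chipRes$fold <- round(chipRes$fold, 4)
  chipRes$log2_fold <- round(chipRes$log2_fold, 4)
  chipRes$spread <- round(chipRes$spread, 4)
  .writeTsv(chipRes, o("chip_enrichment.tsv"),
            .provenance("chip", list(control = ctrlCond)))
  results$chip <- chipRes
  report <- c(report, "", "[chip]",
              sprintf("  %s: fold=%.3g%s", chipRes$condition, chipRes$fold,
                      if ("relative_change" %in% names(chipRes))
                        sprintf(" rel=%.3g", chipRes$relative_change)
                      else ""))

  writeLines(report, o("report.txt"))
  results$reportPath <- o("report.txt")
  invisible(results)
}
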