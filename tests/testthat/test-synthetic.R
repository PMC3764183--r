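# Generators: determinism, truth consistency, planted-signal sanity.

test_that("all generators are deterministic under a fixed seed", {
  e1 <- genExpression(nGenes = 60, seed = 11)
  e2 <- genExpression(nGenes = 60, seed = 11)
  expect_identical(exprsMatrix(e1$bundle), exprsMatrix(e2$bundle))
  expect_identical(detectionCalls(e1$bundle), detectionCalls(e2$bundle))
  n1 <- genNetwork(nNodes = 60, nBlocks = 3, plantedSize = 5, seed = 11)
  n2 <- genNetwork(nNodes = 60, nBlocks = 3, plantedSize = 5, seed = 11)
  expect_identical(igraph::as_edgelist(networkGraph(n1$network)),
                   igraph::as_edgelist(networkGraph(n2$network)))
  expect_identical(tlmGenes(n1$network), tlmGenes(n2$network))
  s1 <- genScreen(seed = 11)$table
  s2 <- genScreen(seed = 11)$table
  expect_identical(s1, s2)
  l1 <- genLane(1250, noiseSd = 2, seed = 11)
  l2 <- genLane(1250, noiseSd = 2, seed = 11)
  expect_identical(intensities(l1), intensities(l2))
  expect_false(identical(intensities(l1),
                         intensities(genLane(1250, noiseSd = 2, seed = 12))))
})

test_that("expression generator plants exactly the contracted DE genes", {
  none <- genExpression(nGenes = 100, deFraction = 0, seed = 1)
  expect_true(all(lengths(plantedDeGenes(none$truth)) == 0))
  sim <- genExpression(nGenes = 1000, deFraction = 0.05, seed = 2)
  de <- plantedDeGenes(sim$truth)
  expect_true(all(lengths(de) == 50))
  genes <- rownames(exprsMatrix(sim$bundle))
  expect_true(all(unlist(de) %in% genes))
  expect_error(genExpression(nGenes = -5), "nGenes")
  expect_error(genExpression(nControl = 0), "nControl")
  expect_error(genExpression(deFraction = 1), "deFraction")
})

test_that("planted genes carry a stronger two-sample t than non-planted genes", {
  ratios <- vapply(1:20, function(s) {
    sim <- genExpression(nGenes = 200, deFraction = 0.1, effect = 0.75,
                         sigma = 0.25, seed = s)
    mat <- exprsMatrix(sim$bundle)
    cond <- sampleConditions(sim$bundle)
    tstat <- abs(apply(mat, 1, function(x)
      pooledT(x[cond == "control"], x[cond == "ethanol"])))
    planted <- rownames(mat) %in% plantedDeGenes(sim$truth)$ethanol
    mean(tstat[planted]) / mean(tstat[!planted])
  }, numeric(1))
  expect_true(all(ratios > 1))
})

test_that("network generator plants a proximal set and rejects degenerate densities", {
  expect_error(genNetwork(pIn = 0.1, pOut = 0.2), "pIn")
  # clique block: every planted pair at distance 1
  cl <- genNetwork(nNodes = 60, nBlocks = 3, pIn = 1, pOut = 0,
                   tlmFraction = 0.3, plantedSize = 10, seed = 3)
  d <- pairwiseDistances(cl$network, plantedProximal(cl$truth))
  expect_true(all(d == 1))
  # planted flags live on TLM nodes; DE non-TLM flags on non-TLM nodes
  nt <- genNetwork(seed = 4)
  expect_true(all(plantedProximal(nt$truth) %in% tlmGenes(nt$network)))
  deAll <- deGenes(nt$network, "ethanol")
  expect_gt(length(setdiff(deAll, tlmGenes(nt$network))), 0)
  # planted pairs are closer than background TLM pairs in most draws
  closer <- vapply(1:20, function(s) {
    g <- genNetwork(pIn = 0.3, pOut = 0.01, plantedSize = 15, seed = s)
    a <- pairwiseDistances(g$network, plantedProximal(g$truth))
    b <- pairwiseDistances(g$network,
                           setdiff(tlmGenes(g$network),
                                   plantedProximal(g$truth)))
    median(a) < median(b)
  }, logical(1))
  expect_gte(sum(closer), 19)
})

test_that("unplanted networks assign DE-TLM labels independent of blocks", {
  g <- genNetwork(planted = FALSE, seed = 5)
  expect_length(plantedProximal(g$truth), 0)
  expect_true(all(intersect(deGenes(g$network, "ethanol"),
                            tlmGenes(g$network)) %in% tlmGenes(g$network)))
})

test_that("screen generator respects the linear model and outlier arithmetic", {
  clean <- genScreen(nMutants = 50, slope = -0.8, intercept = 40,
                     sigma = 1e-9, outlierFraction = 0, seed = 6)$table
  expect_equal(clean$delta, -0.8 * clean$initial + 40, tolerance = 1e-6)
  expect_equal(clean$delta, clean$final - clean$initial)
  scr <- genScreen(nMutants = 100, outlierFraction = 0.05, seed = 7)
  expect_length(plantedOutliers(scr$truth)$ethanol, 5)
  expect_true(all(plantedOutliers(scr$truth)$ethanol %in% scr$table$mutant))
  expect_error(genScreen(sigma = 0), "sigma")
})

test_that("lane generator places the band at the analytic position", {
  lane <- genLane(sqrt(2044 * 779), smearSd = 0.3, baseline = 0,
                  noiseSd = 0, seed = 1)
  expect_equal(positions(lane)[which.max(intensities(lane))], 30,
               tolerance = 1e-3)
  expect_error(genLane(500), "marker range")
  expect_error(genLane(3000), "marker range")
})

test_that("chip generator centers the fold enrichment on the requested truth", {
  reps <- genChip(trueFold = 0.5, nReplicates = 200, cv = 0.1, seed = 8)
  folds <- foldEnrichment(reps$tel_ip, reps$aro_ip, reps$tel_input,
                          reps$aro_input)
  expect_equal(exp(mean(log(folds))), 0.5, tolerance = 0.05)
})
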