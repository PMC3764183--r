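# Shortest-path distances, the rank-sum test and the proximity comparisons.

test_that("edge-list loading builds the documented graph and handles dirt", {
  edges <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb", "b\tc", "a\tc"), edges)
  net <- loadNetwork(edges)
  expect_equal(igraph::vcount(networkGraph(net)), 3)
  expect_equal(igraph::ecount(networkGraph(net)), 3)
  # duplicate edges collapse to one
  writeLines(c("a\tb", "a\tb", "b\ta"), edges)
  expect_message(net2 <- loadNetwork(edges), "collapsed")
  expect_equal(igraph::ecount(networkGraph(net2)), 1)
  # malformed line is reported with its number
  writeLines(c("a\tb", "lonely"), edges)
  expect_error(loadNetwork(edges), "line 2")
  # annotations naming absent genes are dropped with a warning
  writeLines(c("a\tb", "b\tc"), edges)
  tlm <- tempfile(); writeLines(c("a", "zz"), tlm)
  expect_warning(net3 <- loadNetwork(edges, tlm), "absent")
  expect_identical(tlmGenes(net3), "a")
})

test_that("pairwise distances match hand-checkable graphs and reject tiny sets", {
  edges <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc"), edges)
  path <- loadNetwork(edges)
  expect_equal(as.numeric(pairwiseDistances(path, c("a", "c"))), 2)
  clique <- adjToNetwork(matrix(1, 4, 4,
                                dimnames = list(letters[1:4],
                                                letters[1:4])) -
                           diag(4))
  expect_equal(sort(as.numeric(pairwiseDistances(clique, c("a", "b", "c")))),
               c(1, 1, 1))
  expect_error(pairwiseDistances(path, "a"), "at least 2")
  # unreachable pairs are excluded and counted
  writeLines(c("a\tb", "c\td"), edges)
  two <- loadNetwork(edges)
  d <- pairwiseDistances(two, c("a", "b", "c"))
  expect_equal(as.numeric(d), 1)
  expect_equal(attr(d, "nExcluded"), 2)
})

test_that("distances agree with an exhaustive relaxation oracle on random graphs", {
  for (s in 1:30) {
    n <- sample(4:10, 1)
    adj <- randomGraph(n, runif(1, 0.2, 0.7), seed = s)
    net <- adjToNetwork(adj)
    oracle <- fwDistances(adj)
    nodes <- rownames(adj)
    d <- igraph::distances(networkGraph(net), v = nodes, to = nodes)
    expect_equal(d[nodes, nodes], oracle,
                 ignore_attr = TRUE)
    # and the multiset the package reports matches the oracle's upper triangle
    sub <- sample(nodes, 3)
    got <- sort(as.numeric(pairwiseDistances(net, sub)))
    want <- oracle[sub, sub][upper.tri(diag(3))]
    want <- sort(want[is.finite(want)])
    expect_equal(got, want)
  }
})

test_that("distance symmetry holds on random node pairs", {
  nt <- genNetwork(seed = 17)$network
  g <- networkGraph(nt)
  nodes <- igraph::V(g)$name
  set.seed(17)
  for (k in 1:20) {
    uv <- sample(nodes, 2)
    expect_equal(igraph::distances(g, uv[1], uv[2])[1, 1],
                 igraph::distances(g, uv[2], uv[1])[1, 1])
  }
})

test_that("rank-sum p-values match enumeration and the reference implementation", {
  w <- wilcoxonRankSum(c(1, 2), c(3, 4), "less")
  expect_true(w$exact)
  expect_equal(w$p, 1 / 6)
  # same multiset two-sided: p = 1 by symmetry
  expect_equal(wilcoxonRankSum(c(1, 3, 5), c(1, 3, 5), "two.sided")$p, 1)
  # tie-free cases cross-checked against the reference exact test
  set.seed(5)
  for (rep in 1:30) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    vals <- sample(seq(1, 400), nA + nB)   # tie-free by construction
    a <- vals[seq_len(nA)]; b <- vals[-seq_len(nA)]
    for (alt in c("less", "greater", "two.sided")) {
      got <- wilcoxonRankSum(a, b, alt)
      ref <- stats::wilcox.test(a, b, alternative = alt, exact = TRUE)
      expect_true(got$exact)
      expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
      expect_equal(got$statistic, unname(ref$statistic))
    }
  }
  expect_warning(wilcoxonRankSum(c(2, 2), c(2, 2, 2)), "identical")
})

test_that("the normal approximation tracks the exact branch on 8 + 8 samples", {
  set.seed(6)
  for (rep in 1:20) {
    vals <- sample(1:1000, 16)
    a <- vals[1:8]; b <- vals[9:16]
    exact <- wilcoxonRankSum(a, b, "less")$p
    approx <- stats::wilcox.test(a, b, alternative = "less", exact = FALSE,
                                 correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("proximity test separates planted structure and behaves under symmetry", {
  nt <- genNetwork(pIn = 0.3, pOut = 0.01, plantedSize = 15, seed = 21)
  pr <- proximityTest(nt$network, "ethanol")
  expect_lt(pValue(pr), 0.01)
  expect_gte(min(c(proximalDistances(pr), backgroundDistances(pr))), 1)
  # forced symmetry: identical distance multisets give one-sided p >= 0.5
  sym <- wilcoxonRankSum(c(1, 2, 2, 3), c(1, 2, 2, 3), "less")
  expect_gte(sym$p, 0.5)
  expect_error(proximityTest(nt$network, "missing_stress"), "no DE flags")
  # a 1-gene specific set is named in the error
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- letters[1:5]
  tiny <- GeneNetwork(ring, tlm = character(0),
                      deByStress = list(ethanol = character(0)))
  expect_error(proximityTest(tiny, "ethanol"), "0 gene")
})

test_that("specificity control needs a non-TLM DE background and detects planted signal", {
  nt <- genNetwork(pIn = 0.3, pOut = 0.01, plantedSize = 15, seed = 22)
  sc <- specificityControl(nt$network, "ethanol")
  expect_lt(pValue(sc), 0.05)
  # remove the non-TLM DE genes: the control must refuse to run
  noB <- GeneNetwork(networkGraph(nt$network), tlm = tlmGenes(nt$network),
                     deByStress = list(ethanol = intersect(
                       deGenes(nt$network, "ethanol"),
                       tlmGenes(nt$network))))
  expect_error(specificityControl(noB, "ethanol"), "non-TLM")
})

test_that("larger planted sets never weaken the median proximity signal", {
  medLogP <- vapply(c(5, 20), function(k) {
    ps <- vapply(1:15, function(s)
      pValue(proximityTest(genNetwork(plantedSize = k,
                                      seed = s)$network, "ethanol")),
      numeric(1))
    median(-log10(ps))
  }, numeric(1))
  expect_gte(medLogP[2], medLogP[1])
})
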