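# Detection-call filtering, the SAM statistic, s0 tuning, permutation FDR
# and stress-specific set algebra.

test_that("absent-call filter removes majority-absent genes at the documented boundary", {
  set.seed(1)
  mat <- matrix(rnorm(5 * 7), 5, 7,
                dimnames = list(paste0("g", 1:5),
                                paste0("s", 1:7)))
  calls <- matrix("P", 5, 7, dimnames = dimnames(mat))
  calls[1, 1:4] <- "A"   # 4 of 7 absent -> removed (4 > 3.5)
  calls[2, 1:3] <- "A"   # 3 of 7 absent -> kept (3 <= 3.5)
  calls[3, 1:3] <- "M"   # marginal counts as present
  b <- ExpressionBundle(mat, calls, c(rep("control", 4), rep("stress", 3)))
  f <- filterAbsent(b)
  expect_identical(rownames(exprsMatrix(f)), paste0("g", 2:5))
  # idempotence and the all-present identity case
  expect_identical(exprsMatrix(filterAbsent(f)), exprsMatrix(f))
  allP <- tinyBundle(mat, conditions = c(rep("control", 4),
                                         rep("stress", 3)))
  expect_identical(exprsMatrix(filterAbsent(allP)), mat)
})

test_that("SAM statistic reduces to the pooled t at s0 = 0 and shrinks with s0", {
  set.seed(42)
  for (rep in 1:5) {
    mat <- matrix(rnorm(50 * 7), 50, 7,
                  dimnames = list(sprintf("g%02d", 1:50), NULL))
    groups <- factor(rep(c("control", "stress"), c(4, 3)),
                     levels = c("control", "stress"))
    d0 <- samStatistic(mat, groups, s0 = 0)
    tOracle <- apply(mat, 1, function(x)
      pooledT(x[1:4], x[5:7]))
    expect_equal(unname(d0), unname(tOracle), tolerance = 1e-10)
    d1 <- samStatistic(mat, groups, s0 = 0.5)
    d2 <- samStatistic(mat, groups, s0 = 1.0)
    expect_true(all(abs(d2) <= abs(d1) + 1e-12))
  }
  # equal group means give d = 0
  mat <- matrix(rep(1:7, each = 3), 3, 7)
  mat[1, ] <- c(1, 2, 3, 4, 1, 2, 7)   # means 2.5 vs 10/3
  mat[2, ] <- c(0, 0, 2, 2, 0, 1, 2)   # means 1 vs 1
  rownames(mat) <- paste0("g", 1:3)
  groups <- factor(rep(c("a", "b"), c(4, 3)), levels = c("a", "b"))
  expect_equal(unname(samStatistic(mat, groups, s0 = 1)[2]), 0)
  # zero-variance gene is an error without a positive s0
  flat <- matrix(1, 2, 6, dimnames = list(c("g1", "g2"), NULL))
  expect_error(samStatistic(flat, factor(rep(c("a", "b"), each = 3))),
               "zero-variance")
})

test_that("s0 tuning is deterministic and scale-equivariant", {
  set.seed(7)
  mat <- matrix(rnorm(300 * 7, sd = 0.3), 300, 7)
  groups <- factor(rep(c("control", "stress"), c(4, 3)))
  s0a <- chooseS0(mat, groups)
  expect_identical(s0a, chooseS0(mat, groups))
  expect_equal(chooseS0(mat * 3, groups), 3 * s0a, tolerance = 1e-10)
  flat <- matrix(rep(rnorm(7), each = 50), 50, 7, byrow = FALSE)
  expect_warning(s0flat <- chooseS0(flat, groups), "s0 = 0")
  expect_equal(s0flat, 0)
})

test_that("permutation FDR enumerates all 35 label assignments for 4 vs 3 and yields valid q", {
  sim <- genExpression(nGenes = 200, deFraction = 0.1, seed = 3)
  b <- filterAbsent(sim$bundle)
  res <- samFdr(b, "ethanol", nPerm = 100, seed = 3)
  expect_identical(res@nPerm, as.integer(choose(7, 4)))
  q <- samQValues(res)
  expect_true(all(q >= 0 & q <= 1))
  # q is monotone non-increasing in |d|
  ord <- order(abs(samScores(res)), decreasing = TRUE)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_setequal(significantGenes(res), names(q)[q < 0.01])
  # planted genes dominate the significant list
  planted <- plantedDeGenes(sim$truth)$ethanol
  sig <- significantGenes(res)
  if (length(sig) > 0)
    expect_gt(mean(sig %in% planted), 0.8)
  expect_error(samFdr(b, "ethanol", nPerm = 10), "nPerm")
  expect_error(samFdr(b, "nonexistent"), "lacks samples")
})

test_that("the conservative false-count variant controls type-I error on null data", {
  any1 <- vapply(1:30, function(s) {
    sim <- genExpression(nGenes = 1000, deFraction = 0, seed = s)
    length(significantGenes(samFdr(filterAbsent(sim$bundle), "ethanol",
                                   seed = s, fpSummary = "q90"))) > 0
  }, logical(1))
  expect_lte(mean(any1), 0.1)
})

test_that("stress-specific sets follow the Venn-region algebra", {
  de <- list(ethanol = c("g1", "g2"), caffeine = c("g2", "g3"))
  sets <- stressSpecificSets(de)
  expect_identical(specificSets(sets)$ethanol, "g1")
  expect_identical(specificSets(sets)$caffeine, "g3")
  # identical DE sets leave all specific sets empty
  same <- stressSpecificSets(list(a = c("g1", "g2"), b = c("g1", "g2")))
  expect_true(all(lengths(specificSets(same)) == 0))
  # disjoint DE sets are their own specific sets
  disj <- list(a = c("g1"), b = c("g2"), c = c("g3"), d = c("g4"))
  expect_identical(specificSets(stressSpecificSets(disj)), disj)
  expect_error(stressSpecificSets(de, list(up = "unknown_stress")),
               "unknown")
  expect_error(stressSpecificSets(list(a = "g1")), "two stresses")
})

test_that("specific sets are pairwise disjoint on random inputs", {
  set.seed(9)
  for (rep in 1:10) {
    de <- lapply(1:4, function(i)
      sample(sprintf("g%03d", 1:60), sample(5:30, 1)))
    names(de) <- paste0("s", 1:4)
    sp <- specificSets(stressSpecificSets(de))
    for (i in 1:3) for (j in (i + 1):4)
      expect_length(intersect(sp[[i]], sp[[j]]), 0)
  }
})

test_that("direction-specific sets require DE everywhere inside the group and nowhere outside", {
  de <- list(ethanol = c("g1", "g2", "g5"),
             caffeine = c("g2", "g3", "g4"),
             heat = c("g3", "g4", "g2"),
             H2O2 = c("g4"))
  sets <- stressSpecificSets(de, list(
    elongating = "ethanol", shortening = c("caffeine", "heat"),
    neutral = "H2O2"))
  ds <- directionSpecificSets(sets)
  expect_identical(ds$elongating, c("g1", "g5"))  # g2 is DE under shortening
  expect_identical(ds$shortening, "g3")           # g2 in ethanol, g4 in H2O2
  expect_length(ds$neutral, 0)                    # g4 DE under shortening
})
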