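# Pearson correlation, robust fitting and outlier calling for the
# responsiveness screen.

test_that("pearson matches the closed formula and the reference implementation", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  got <- pearsonCorrelation(x, y)
  # brute-force covariance formula
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    ((length(x) - 1) * sd(x) * sd(y))
  expect_equal(got$r, rOracle, tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_error(pearsonCorrelation(x, rep(2, 4)), "'y'")
  expect_error(pearsonCorrelation(x, c(1, 2)), "equal length")
})

test_that("pearson is affine invariant up to the sign of the rescaling", {
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    a <- runif(1, -3, 3); c <- runif(1, -3, 3)
    if (a == 0 || c == 0) next
    r0 <- pearsonCorrelation(x, y)$r
    r1 <- pearsonCorrelation(a * x + 2, c * y - 7)$r
    expect_equal(r1, sign(a * c) * r0, tolerance = 1e-10)
  }
})

test_that("robust fit recovers a noiseless line exactly", {
  x <- seq(150, 450, length.out = 30)
  fit <- robustFit(x, -0.8 * x + 40)
  expect_equal(coef(fit)[["slope"]], -0.8, tolerance = 1e-6)
  expect_equal(coef(fit)[["intercept"]], 40, tolerance = 1e-6)
  expect_true(fit@converged)
  expect_equal(fitScale(fit), 0)
})

test_that("robust fit resists contamination where ordinary least squares does not", {
  errRob <- errOls <- numeric(15)
  for (s in 1:15) {
    scr <- genScreen(nMutants = 100, slope = -0.8, intercept = 40,
                     sigma = 10, outlierFraction = 0.1, outlierShift = 80,
                     seed = s)
    fit <- robustFit(scr$table$initial, scr$table$delta)
    ols <- coef(lm(delta ~ initial, data = scr$table))
    errRob[s] <- abs(coef(fit)[["slope"]] - (-0.8))
    errOls[s] <- abs(ols[["initial"]] - (-0.8))
    expect_equal(residuals(fit),
                 scr$table$delta - (coef(fit)[["slope"]] *
                                      scr$table$initial +
                                      coef(fit)[["intercept"]]),
                 tolerance = 1e-10)
    expect_true(all(weights(fit) >= 0 & weights(fit) <= 1))
  }
  expect_lt(median(errRob), median(errOls))
  expect_gt(mean(errRob <= 0.05 * 0.8), 0.9)
})

test_that("robust fit agrees with an independent M-estimator on contaminated data", {
  scr <- genScreen(nMutants = 100, outlierFraction = 0.1, seed = 99)
  fit <- robustFit(scr$table$initial, scr$table$delta)
  ref <- MASS::rlm(delta ~ initial, data = scr$table,
                   psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  expect_equal(coef(fit)[["slope"]], unname(coef(ref)["initial"]),
               tolerance = 0.02)
})

test_that("breakdown: contaminated slope error stays within 2x the clean error", {
  err <- function(outFrac) median(vapply(1:15, function(s) {
    scr <- genScreen(nMutants = 100, outlierFraction = outFrac,
                     outlierShift = 80, seed = s)
    abs(coef(robustFit(scr$table$initial, scr$table$delta))[["slope"]] +
          0.8)
  }, numeric(1)))
  expect_lte(err(0.10), 2 * err(0) + 1e-6)
})

test_that("outlier calling flags the extreme tails with the right direction labels", {
  scr <- genScreen(nMutants = 100, outlierFraction = 0.05,
                   outlierShift = 80, seed = 12)
  fit <- robustFit(scr$table$initial, scr$table$delta)
  calls <- callOutliers(fit, alpha = 0.05, stressDirection = "elongating",
                        method = "rank", mutants = scr$table$mutant)
  truth <- plantedOutliers(scr$truth)$ethanol
  expect_gte(mean(truth %in% calls$mutant[calls$flagged]), 0.8)
  # direction: positive residual under elongation = over-responsive
  expect_true(all(calls$direction[calls$z > 0] == "over_responsive"))
  expect_true(all(calls$direction[calls$z < 0] == "under_responsive"))
  under <- callOutliers(fit, stressDirection = "shortening",
                        mutants = scr$table$mutant)
  expect_true(all(under$direction[under$z > 0] == "under_responsive"))
  # vanishing alpha flags nothing on clean data under the normal rule
  clean <- genScreen(nMutants = 100, outlierFraction = 0, seed = 13)
  cleanFit <- robustFit(clean$table$initial, clean$table$delta)
  none <- callOutliers(cleanFit, alpha = 1e-12,
                       stressDirection = "elongating")
  expect_false(any(none$flagged))
  # degenerate fits are refused
  x <- seq(150, 450, length.out = 30)
  exact <- robustFit(x, -0.8 * x + 40)
  expect_error(callOutliers(exact, stressDirection = "elongating"),
               "scale")
  expect_error(callOutliers(fit, alpha = 0.6,
                            stressDirection = "elongating"), "alpha")
})

test_that("screen tables recompute delta and refuse inconsistent input", {
  tab <- data.frame(mutant = c("m1", "m2"), initial = c(300, 350),
                    final = c(380, 310))
  out <- checkScreenTable(tab)
  expect_equal(out$delta, c(80, -40))
  tab$delta <- c(80, -45)
  expect_error(checkScreenTable(tab), "disagrees")
  tab$delta <- c(80.4, -40.4)   # within 1 bp: accepted, recomputed
  expect_equal(checkScreenTable(tab)$delta, c(80, -40))
})

test_that("response ratios flag zero deltas and are scale-stable in ordering", {
  rr <- responseRatio(c(200, 300, 150), c(100, 0, -50))
  expect_equal(rr$ratio[1], 2)
  expect_true(rr$infinite[2])
  expect_equal(rr$ratio[3], -3)
  r1 <- responseRatio(c(200, 300, 150), c(100, 50, -50))$ratio
  r2 <- responseRatio(10 * c(200, 300, 150), 10 * c(100, 50, -50))$ratio
  expect_identical(order(r1), order(r2))
})
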