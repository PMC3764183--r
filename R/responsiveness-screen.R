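## Responsiveness screen: the linear relation between a mutant's initial
## telomere length and its length change under stress, fit robustly, with
## over/under-responsive mutants called as extreme standardized residuals.

#' Pearson correlation with the t-transform p-value
#'
#' @param x numeric values
#' @param y numeric values, same length (>= 3)
#' @return list with `r`, `p` (two-sided, t transform on n - 2 df), `n`
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0) stop("'x' has zero variance")
  if (sd(y) == 0) stop("'y' has zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Validate and complete a screen table
#'
#' Checks the (mutant, initial, final[, delta]) table for one stress:
#' recomputes `delta = final - initial` and rejects a supplied delta column
#' that disagrees by more than 1 bp.
#'
#' @param tab data.frame with columns `mutant`, `initial`, `final` and
#'   optionally `delta` (bp)
#' @return the table with a consistent `delta` column
#' @export
checkScreenTable <- function(tab) {
  need <- c("mutant", "initial", "final")
  if (!all(need %in% names(tab)))
    stop("screen table must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$mutant))
    stop("duplicate mutant IDs in screen table")
  delta <- tab$final - tab$initial
  if ("delta" %in% names(tab) && any(abs(tab$delta - delta) > 1))
    stop("supplied 'delta' disagrees with final - initial by > 1 bp")
  tab$delta <- delta
  tab
}

#' Robust linear fit of length change on initial length
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685): starting from ordinary least squares, each
#' iteration re-estimates the scale as 1.4826 x the median absolute
#' deviation of the residuals, recomputes bisquare weights, and solves the
#' weighted least-squares problem, until the relative coefficient change
#' drops below `tol` or `maxIter` iterations. An exact (zero-residual) fit
#' returns immediately with scale 0.
#'
#' @param initial initial telomere lengths (bp)
#' @param delta length changes (bp)
#' @param tuning bisquare tuning constant
#' @param maxIter iteration cap
#' @param tol relative coefficient-change tolerance
#' @return a [RegressionFit-class]; non-convergence is reported with
#'   `converged = FALSE` and a warning, not an error
#' @examples
#' x <- seq(150, 450, length.out = 20)
#' robustFit(x, -0.8 * x + 40)
#' @export
robustFit <- function(initial, delta, tuning = 4.685, maxIter = 50,
                      tol = 1e-8) {
  if (length(initial) != length(delta))
    stop("'initial' and 'delta' must have equal length")
  n <- length(initial)
  if (n < 10) warning("fewer than 10 mutants; robust fit may be unstable")
  X <- cbind(1, initial)
  beta <- qr.solve(X, delta)
  w <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  scale <- NA_real_
  for (iter in seq_len(maxIter)) {
    resid <- as.numeric(delta - X %*% beta)
    scale <- 1.4826 * median(abs(resid - median(resid)))
    if (scale < 1e-10 * max(1, mad(delta))) {
      scale <- 0
      w <- rep(1, n)
      converged <- TRUE
      break
    }
    u <- resid / (tuning * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    fit <- lm.wfit(X, delta, w)
    newBeta <- fit$coefficients
    if (max(abs(newBeta - beta)) <= tol * max(abs(beta), 1)) {
      beta <- newBeta
      converged <- TRUE
      break
    }
    beta <- newBeta
  }
  if (!converged)
    warning("IRLS did not converge in ", maxIter, " iterations")
  resid <- as.numeric(delta - X %*% beta)
  if (scale > 0)
    scale <- 1.4826 * median(abs(resid - median(resid)))
  new("RegressionFit", slope = unname(beta[2]), intercept = unname(beta[1]),
      scale = scale, weights = pmin(pmax(as.numeric(w), 0), 1),
      residuals = resid, converged = converged, nIter = iter)
}

#' Call over- and under-responsive mutants from a robust fit
#'
#' Standardizes residuals by the robust scale and flags the most extreme
#' fraction `alpha` (alpha/2 from each side): under the default normal rule,
#' mutants with |z| above the standard normal upper alpha/2 quantile
#' (1.960 at alpha = 0.05). The rank-based variant flags the literal top
#' and bottom ceiling(n * alpha / 2) residuals instead. Direction: under an
#' elongating stress a positive residual means the mutant elongated more
#' than its initial length predicts (over-responsive); under a shortening
#' stress a negative residual is over-responsive.
#'
#' @param fit a [RegressionFit-class] with positive scale
#' @param alpha total flagged tail probability, in (0, 0.5); the published
#'   screen used 0.05
#' @param stressDirection `"elongating"` or `"shortening"`
#' @param method `"normal"` (quantile cut on z) or `"rank"`
#' @param mutants optional mutant IDs, recycled into the output
#' @return data.frame: mutant, z, flagged, direction
#' @export
callOutliers <- function(fit, alpha = 0.05,
                         stressDirection = c("elongating", "shortening"),
                         method = c("normal", "rank"), mutants = NULL) {
  stopifnot(is(fit, "RegressionFit"))
  stressDirection <- match.arg(stressDirection)
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must lie in (0, 0.5)")
  if (fit@scale <= 0)
    stop("degenerate fit: scale is zero, residuals cannot be standardized")
  z <- fit@residuals / fit@scale
  n <- length(z)
  if (method == "normal") {
    cut <- qnorm(1 - alpha / 2)
    flagged <- abs(z) > cut
  } else {
    k <- ceiling(n * alpha / 2)
    ord <- order(z)
    flagged <- logical(n)
    if (k > 0) flagged[c(head(ord, k), utils::tail(ord, k))] <- TRUE
  }
  expectedSign <- if (stressDirection == "elongating") 1 else -1
  direction <- ifelse(sign(z) == expectedSign,
                      "over_responsive", "under_responsive")
  direction[z == 0] <- "neutral"
  if (is.null(mutants)) mutants <- sprintf("m%03d", seq_len(n))
  data.frame(mutant = mutants, z = z, flagged = flagged,
             direction = direction, stringsAsFactors = FALSE)
}

#' Ratio of initial length to length change
#'
#' The grouping quantity used for the very short mutants: initial length
#' divided by the elongation after 100 generations. A zero delta is
#' reported as an infinite ratio with a flag rather than an error.
#'
#' @param initial initial lengths (bp)
#' @param delta length changes (bp)
#' @return data.frame: ratio, infinite (flag)
#' @export
responseRatio <- function(initial, delta) {
  if (length(initial) != length(delta))
    stop("'initial' and 'delta' must have equal length")
  ratio <- ifelse(delta == 0, Inf * sign(initial), initial / delta)
  data.frame(ratio = ratio, infinite = delta == 0)
}
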