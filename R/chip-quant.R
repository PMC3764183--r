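## ChIP quantification: telomere fold enrichment/depletion normalized to
## the ARO1 control locus and to input chromatin.

#' ChIP fold enrichment at the telomere
#'
#' The ratio-of-ratios [telIP / ARO1IP] / [tel input / ARO1 input]:
#' telomeric IP signal normalized to the control-locus IP signal, divided
#' by the same ratio in input chromatin. Degree-0 homogeneous: rescaling
#' all four quantities by a common factor leaves it unchanged. Vectorized
#' over replicates.
#'
#' @param telIp telomeric IP signal(s), > 0
#' @param aroIp control-locus (ARO1) IP signal(s), > 0
#' @param telInput telomeric input signal(s), > 0
#' @param aroInput control-locus input signal(s), > 0
#' @return fold enrichment (dimensionless)
#' @examples
#' foldEnrichment(8, 2, 2, 1)   # 2.0
#' @export
foldEnrichment <- function(telIp, aroIp, telInput, aroInput) {
  vals <- list(telIp = telIp, aroIp = aroIp,
               telInput = telInput, aroInput = aroInput)
  for (nm in names(vals))
    if (any(!is.finite(vals[[nm]]) | vals[[nm]] <= 0))
      stop("'", nm, "' must be strictly positive")
  (telIp / aroIp) / (telInput / aroInput)
}

#' Convert qPCR Ct values to relative quantities
#'
#' quantity = efficiency^(-Ct); with perfect doubling (efficiency 2) one
#' cycle earlier means twice the template.
#'
#' @param ct cycle-threshold values
#' @param efficiency per-cycle amplification factor
#' @return relative quantities
#' @export
ctToQuantity <- function(ct, efficiency = 2) {
  if (efficiency <= 1) stop("'efficiency' must exceed 1")
  efficiency^(-ct)
}

#' Summarize replicate ChIP measurements for one condition
#'
#' Folds are ratio-scale, so replicates are combined by geometric mean;
#' the spread is the SD of the per-replicate log2 folds. An arithmetic-mean
#' summary is available behind `summary = "arithmetic"`.
#'
#' @param measurements data.frame with columns condition, replicate,
#'   tel_ip, aro_ip, tel_input, aro_input (one condition only)
#' @param summary `"geometric"` (default) or `"arithmetic"`
#' @return an [EnrichmentResult-class]
#' @export
summarizeReplicates <- function(measurements,
                                summary = c("geometric", "arithmetic")) {
  summary <- match.arg(summary)
  need <- c("condition", "tel_ip", "aro_ip", "tel_input", "aro_input")
  if (!all(need %in% names(measurements)))
    stop("measurements must contain columns: ", paste(need, collapse = ", "))
  if (nrow(measurements) < 1) stop("at least one replicate is required")
  if (length(unique(measurements$condition)) != 1L)
    stop("mixed conditions; summarize one condition at a time")
  folds <- foldEnrichment(measurements$tel_ip, measurements$aro_ip,
                          measurements$tel_input, measurements$aro_input)
  fold <- if (summary == "geometric") exp(mean(log(folds))) else mean(folds)
  spread <- if (length(folds) > 1) sd(log2(folds)) else 0
  new("EnrichmentResult", fold = fold, log2Fold = log2(fold),
      spread = spread, nReplicates = nrow(measurements),
      condition = as.character(measurements$condition[1]))
}

#' Relative change in fold enrichment between conditions
#'
#' stress fold divided by control fold: 0.5 means a two-fold reduction of
#' the protein's telomere association under stress.
#'
#' @param stress an [EnrichmentResult-class] (or a positive fold)
#' @param control an [EnrichmentResult-class] (or a positive fold)
#' @return dimensionless ratio
#' @export
relativeChange <- function(stress, control) {
  f1 <- if (is(stress, "EnrichmentResult")) foldValue(stress)
        else as.numeric(stress)
  f2 <- if (is(control, "EnrichmentResult")) foldValue(control)
        else as.numeric(control)
  if (f1 <= 0 || f2 <= 0) stop("folds must be positive")
  f1 / f2
}

#' Per-condition enrichment summary of a ChIP table
#'
#' @param tab data.frame with columns condition, replicate, tel_ip, aro_ip,
#'   tel_input, aro_input; or Ct-mode columns (same names suffixed `_ct`)
#'   converted via [ctToQuantity()]
#' @param efficiency qPCR efficiency for Ct-mode input
#' @return data.frame: condition, fold, log2_fold, spread, n
#' @export
chipSummary <- function(tab, efficiency = 2) {
  ctCols <- paste0(c("tel_ip", "aro_ip", "tel_input", "aro_input"), "_ct")
  if (all(ctCols %in% names(tab))) {
    for (base in c("tel_ip", "aro_ip", "tel_input", "aro_input"))
      tab[[base]] <- ctToQuantity(tab[[paste0(base, "_ct")]], efficiency)
  }
  res <- lapply(split(tab, tab$condition), summarizeReplicates)
  out <- data.frame(
    condition = vapply(res, function(r) r@condition, character(1)),
    fold = vapply(res, function(r) r@fold, numeric(1)),
    log2_fold = vapply(res, function(r) r@log2Fold, numeric(1)),
    spread = vapply(res, function(r) r@spread, numeric(1)),
    n = vapply(res, function(r) r@nReplicates, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$condition), , drop = FALSE]
}
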