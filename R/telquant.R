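## Telomere fragment length estimation from 1-D lane densitometry,
## calibrated on two size-marker bands.

#' Calibrate a log-linear size/migration mapping from two marker bands
#'
#' Fits the standard gel-electrophoresis model log10(size) = intercept +
#' slope * position through the two marker points. With exactly two markers
#' the interpolation is exact: both marker sizes are reproduced to machine
#' precision, and the mapping is independent of marker order.
#'
#' @param markerPositions migration coordinates of the two marker bands
#' @param markerSizes fragment sizes (bp) of the two marker bands
#' @return a [SizeCalibration-class]
#' @examples
#' cal <- calibrateSizes(c(10, 50), c(2044, 779))
#' sizeAt(cal, 30)   # geometric mean of the marker sizes, ~1261.9 bp
#' @export
calibrateSizes <- function(markerPositions, markerSizes) {
  if (length(markerPositions) != 2L || length(markerSizes) != 2L)
    stop("exactly two marker bands are required")
  if (markerPositions[1] == markerPositions[2])
    stop("marker positions must be distinct")
  if (markerSizes[1] == markerSizes[2])
    stop("marker sizes must be distinct")
  if (any(markerSizes <= 0))
    stop("marker sizes must be positive")
  slope <- (log10(markerSizes[2]) - log10(markerSizes[1])) /
    (markerPositions[2] - markerPositions[1])
  intercept <- log10(markerSizes[1]) - slope * markerPositions[1]
  new("SizeCalibration", slope = slope, intercept = intercept)
}

#' Map a migration position to a fragment size
#'
#' @param calib a [SizeCalibration-class]
#' @param position migration coordinate(s)
#' @return fragment size(s) in bp
#' @export
sizeAt <- function(calib, position) {
  stopifnot(is(calib, "SizeCalibration"))
  10^(calib@intercept + calib@slope * position)
}

#' Map a fragment size to its migration position
#'
#' Inverse of [sizeAt()].
#'
#' @param calib a [SizeCalibration-class]
#' @param size fragment size(s) in bp
#' @return migration coordinate(s)
#' @export
positionOf <- function(calib, size) {
  stopifnot(is(calib, "SizeCalibration"))
  if (any(size <= 0)) stop("size must be positive")
  (log10(size) - calib@intercept) / calib@slope
}

#' Subtract a quantile background from a lane profile
#'
#' Subtracts the stated intensity quantile from the whole trace and clips
#' negatives to zero. Idempotent on an all-zero profile.
#'
#' @param profile a [LaneProfile-class]
#' @param quantile background quantile in (0, 0.5]
#' @return the background-corrected [LaneProfile-class], with the subtracted
#'   level attached as attribute `"background"`
#' @export
subtractBackground <- function(profile, quantile = 0.1) {
  stopifnot(is(profile, "LaneProfile"))
  if (quantile <= 0 || quantile > 0.5)
    stop("quantile must lie in (0, 0.5]")
  bg <- as.numeric(stats::quantile(profile@intensities, quantile))
  out <- LaneProfile(profile@positions,
                     pmax(profile@intensities - bg, 0),
                     profile@markerPositions, profile@markerSizes)
  attr(out, "background") <- bg
  out
}

#' Detect the telomeric smear around the lane's intensity peak
#'
#' Returns the maximal contiguous position interval around the global
#' intensity maximum over which the intensity stays at or above
#' `thresholdFraction` of the peak. The profile is assumed
#' background-corrected (see [subtractBackground()]).
#'
#' @param profile a [LaneProfile-class], background already subtracted
#' @param thresholdFraction fraction of the peak intensity in (0, 1)
#' @return numeric of length 2: the interval's start and end positions, with
#'   the sample indices attached as attribute `"indices"`
#' @export
detectSmear <- function(profile, thresholdFraction = 0.2) {
  stopifnot(is(profile, "LaneProfile"))
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  y <- profile@intensities
  if (all(y == 0))
    stop("no signal: profile is all zero after background subtraction")
  ipk <- which.max(y)
  thr <- thresholdFraction * y[ipk]
  lo <- ipk
  while (lo > 1L && y[lo - 1L] >= thr) lo <- lo - 1L
  hi <- ipk
  while (hi < length(y) && y[hi + 1L] >= thr) hi <- hi + 1L
  out <- c(profile@positions[lo], profile@positions[hi])
  attr(out, "indices") <- c(lo, hi)
  out
}

#' Estimate telomere fragment length from a lane profile
#'
#' The full lane workflow: quantile background subtraction, smear detection
#' around the peak, then mapping the intensity-weighted centroid position of
#' the smear to bp through the marker calibration. The centroid is computed
#' in migration space, so it is exact for symmetric bands. The smear bounds
#' are mapped to bp as `smearLo`/`smearHi` (migration reverses size order:
#' the far edge of the smear is the smaller fragment).
#'
#' @param profile a [LaneProfile-class] (raw; background handled internally)
#' @param calib optional [SizeCalibration-class]; by default derived from the
#'   profile's own marker bands
#' @param thresholdFraction smear threshold as a fraction of peak, in (0, 1)
#' @param backgroundQuantile background quantile passed to
#'   [subtractBackground()]
#' @return a [LengthEstimate-class]
#' @examples
#' lane <- genLane(1250, seed = 1)
#' estimateLength(lane)
#' @export
estimateLength <- function(profile, calib = NULL, thresholdFraction = 0.2,
                           backgroundQuantile = 0.1) {
  stopifnot(is(profile, "LaneProfile"))
  if (is.null(calib))
    calib <- calibrateSizes(profile@markerPositions, profile@markerSizes)
  corrected <- subtractBackground(profile, backgroundQuantile)
  bg <- attr(corrected, "background")
  smear <- detectSmear(corrected, thresholdFraction)
  idx <- attr(smear, "indices")
  mrange <- range(profile@markerPositions)
  if (smear[1] < mrange[1])
    stop(sprintf(
      "smear start %.3g migrates less than the large marker at %.3g; size would be extrapolated",
      smear[1], mrange[1]))
  if (smear[2] > mrange[2])
    stop(sprintf(
      "smear end %.3g migrates beyond the small marker at %.3g; size would be extrapolated",
      smear[2], mrange[2]))
  pos <- corrected@positions[idx[1]:idx[2]]
  wts <- corrected@intensities[idx[1]:idx[2]]
  centroid <- sum(pos * wts) / sum(wts)
  sizes <- sizeAt(calib, c(centroid, smear[1], smear[2]))
  new("LengthEstimate", length = sizes[1],
      smearLo = min(sizes[2:3]), smearHi = max(sizes[2:3]),
      background = bg)
}

#' Telomere length difference between stress and control lanes
#'
#' Positive values mean the stress lane carries longer telomeres
#' (elongation); negative values mean shortening.
#'
#' @param stress a [LengthEstimate-class] from the stress lane
#' @param control a [LengthEstimate-class] from the control lane
#' @return length difference in bp
#' @export
deltaLength <- function(stress, control) {
  stopifnot(is(stress, "LengthEstimate"), is(control, "LengthEstimate"))
  stress@length - control@length
}
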