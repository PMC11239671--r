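# Boltzmann sigmoid of the calibration curve and its inverse.
calibForward <- function(calib, ratio) {
  calib@pHmin + (calib@pHmax - calib@pHmin) /
    (1 + exp((calib@ratioHalf - ratio) / calib@slope))
}

#' Inverse calibration: the ratio corresponding to a pH
#'
#' @param calib a [CalibCurve-class].
#' @param pH pH value(s) strictly inside `(pHmin, pHmax)`.
#' @return The 405:475 ratio(s).
#' @export
calibInverse <- function(calib, pH) {
  stopifnot(is(calib, "CalibCurve"))
  if (any(pH <= calib@pHmin) || any(pH >= calib@pHmax))
    stop("pH outside the calibration domain (",
         calib@pHmin, ", ", calib@pHmax, ")")
  frac <- (pH - calib@pHmin) / (calib@pHmax - calib@pHmin)
  calib@ratioHalf - calib@slope * log(1 / frac - 1)
}

#' 405:475 fluorescence ratio series
#'
#' @param traces a [FluorTraces-class]; all 475 nm samples must be
#'   positive.
#' @return Data frame `t_s`, `ratio`.
#' @examples
#' cal <- boltzmannCalib()
#' tr <- genPhTraces(6.3, cal, seed = 1)
#' head(ratioSeries(tr))
#' @export
ratioSeries <- function(traces) {
  stopifnot(is(traces, "FluorTraces"))
  bad <- which(traces@f475 <= 0)
  if (length(bad))
    stop("non-positive 475 nm intensity at index ", bad[1])
  data.frame(t_s = traces@tS, ratio = traces@f405 / traces@f475)
}

#' Fit a Boltzmann calibration curve to pH standards
#'
#' Least-squares Boltzmann sigmoid fit of pH against measured ratio, the
#' standard treatment for ratiometric pHluorin calibration. The standards
#' must be monotone in ratio (up to noise); monotonicity of the fitted
#' curve over the standards' range is verified.
#'
#' @param pH standard pH values (>= 4 values spanning the range).
#' @param ratio measured 405:475 ratios, one per standard.
#' @param pHmargin how far the fitted asymptotes are allowed to start
#'   beyond the standards' pH range in the initial values.
#' @return A [CalibCurve-class] with `residualSD` from the fit.
#' @examples
#' truth <- boltzmannCalib(5, 9, 1, 0.3)
#' phs <- seq(5.5, 8.5, by = 0.5)
#' fit <- fitCalibration(phs, calibInverse(truth, phs))
#' @export
fitCalibration <- function(pH, ratio, pHmargin = 1) {
  stopifnot(length(pH) == length(ratio))
  if (length(pH) < 4L) stop("at least 4 standards are required")
  rho <- stats::cor(pH, ratio, method = "spearman")
  if (!is.finite(rho) || abs(rho) < 0.9)
    stop("standards are not monotone in ratio")
  df <- data.frame(r = ratio, p = pH)
  start <- list(pHmin = min(pH) - pHmargin, pHmax = max(pH) + pHmargin,
                ratioHalf = stats::median(ratio),
                slope = if (rho >= 0) diff(range(ratio)) / 4
                        else -diff(range(ratio)) / 4)
  fit <- minpack.lm::nlsLM(
    p ~ pHmin + (pHmax - pHmin) / (1 + exp((ratioHalf - r) / slope)),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- as.list(stats::coef(fit))
  calib <- new("CalibCurve", pHmin = cf$pHmin, pHmax = cf$pHmax,
               ratioHalf = cf$ratioHalf, slope = cf$slope,
               residualSD = stats::sigma(fit),
               ratioRange = range(ratio))
  grid <- seq(min(ratio), max(ratio), length.out = 101)
  if (any(diff(calibForward(calib, grid)) * sign(cf$slope) < 0))
    stop("fitted calibration is not monotone over the standards' range")
  calib
}

#' Convert ratios to pH through a calibration curve
#'
#' @param ratio 405:475 ratio(s) inside the calibration's valid range.
#' @param calib a [CalibCurve-class].
#' @return pH value(s).
#' @examples
#' cal <- boltzmannCalib()
#' ratioToPH(calibInverse(cal, 6.3), cal)  # 6.3
#' @export
ratioToPH <- function(ratio, calib) {
  stopifnot(is(calib, "CalibCurve"))
  if (any(ratio < calib@ratioRange[1]) || any(ratio > calib@ratioRange[2]))
    stop("ratio outside the calibration's valid range [",
         calib@ratioRange[1], ", ", calib@ratioRange[2], "]")
  calibForward(calib, ratio)
}

#' Resting pH and NH4Cl buffering response
#'
#' The resting pH is the mean over the `preWindowS` seconds preceding the
#' stimulus onset; the post-stimulus pH is read at `onsetS + postOffsetS`
#' (nearest sample); the buffering response is their difference.
#'
#' @param phSeries pH values, one per time point.
#' @param tS matching time base in seconds.
#' @param onsetS stimulus onset (s), default the 30 s convention.
#' @param preWindowS pre-stimulus averaging window (s).
#' @param postOffsetS offset of the post-stimulus read-out time (s).
#' @return A list with `restingPH`, `postPH`, `deltaPH`.
#' @examples
#' t <- 0:120
#' ph <- ifelse(t < 30, 6.3, 7.1)
#' bufferingResponse(ph, t)
#' @export
bufferingResponse <- function(phSeries, tS, onsetS = 30, preWindowS = 10,
                              postOffsetS = 10) {
  stopifnot(length(phSeries) == length(tS))
  if (onsetS <= min(tS) || onsetS > max(tS))
    stop("stimulus onset outside the trace")
  if (onsetS - preWindowS < min(tS))
    stop("pre-stimulus window extends before the trace start")
  tPost <- onsetS + postOffsetS
  if (tPost > max(tS))
    stop("post-stimulus time beyond the trace end")
  pre <- tS >= (onsetS - preWindowS) & tS < onsetS
  if (!any(pre)) stop("no samples in the pre-stimulus window")
  restingPH <- mean(phSeries[pre])
  postPH <- phSeries[which.min(abs(tS - tPost))]
  list(restingPH = restingPH, postPH = postPH,
       deltaPH = postPH - restingPH)
}
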