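#' @describeIn GatingModel-class compact display
#' @param object object to display
#' @export
setMethod("show", "GatingModel", function(object) {
  cat("GatingModel with", length(object@stateLabels), "states:",
      paste(object@stateLabels, collapse = ", "), "\n")
  cat("  conductance (pS):", paste(object@conductancePS, collapse = ", "),
      " Erev:", object@erevMV, "mV\n")
})

#' @describeIn EventSequence-class compact display
#' @param object object to display
#' @export
setMethod("show", "EventSequence", function(object) {
  cat("EventSequence:", length(object@states), "events,",
      sprintf("%.1f ms total\n", object@totalMS))
  if (length(object@states)) {
    tab <- tapply(object@durationsMS, object@states, sum)
    for (s in names(tab))
      cat(sprintf("  %-8s %8.1f ms (%.3f)\n", s, tab[[s]],
                  tab[[s]] / object@totalMS))
  }
})

#' @describeIn TraceRecord-class compact display
#' @param object object to display
#' @export
setMethod("show", "TraceRecord", function(object) {
  cat(sprintf("TraceRecord: %d samples at %g kHz (%.1f ms), holding %g mV\n",
              length(object@iPA), object@samplingKHz,
              length(object@iPA) / object@samplingKHz, object@holdingMV))
  if (!is.na(object@filterKHz))
    cat("  low-pass filtered at", object@filterKHz, "kHz\n")
})

#' @describeIn DoseResponse-class compact display
#' @param object object to display
#' @export
setMethod("show", "DoseResponse", function(object) {
  cat("DoseResponse:", length(unique(object@concentrationUM)),
      "concentrations x", length(unique(object@replicate)), "replicates\n")
})

#' @describeIn FluorTraces-class compact display
#' @param object object to display
#' @export
setMethod("show", "FluorTraces", function(object) {
  cat(sprintf(
    "FluorTraces: %d time points (%.0f-%.0f s), stimulus onset %g s\n",
    length(object@tS), min(object@tS), max(object@tS),
    object@stimulusOnsetS))
})

#' @describeIn DwellFit-class compact display
#' @param object object to display
#' @export
setMethod("show", "DwellFit", function(object) {
  cat(sprintf("DwellFit: tau = %.3f ms (n = %d, dead time %g ms)\n",
              object@tauMS, object@nEvents, object@deadTimeMS))
})

#' @describeIn AmpHistFit-class compact display
#' @param object object to display
#' @export
setMethod("show", "AmpHistFit", function(object) {
  cat("AmpHistFit with", length(object@means), "Gaussian components\n")
  for (i in seq_along(object@means))
    cat(sprintf("  mean %7.3f pA  sd %6.3f pA  weight %.3f\n",
                object@means[i], object@sds[i], object@weights[i]))
  cat(sprintf("  peak separation / SD: %.2f\n", object@separation))
})

#' @describeIn HillFit-class compact display
#' @param object object to display
#' @export
setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: IC50 = %.4g uM, h = %.4f (residual SD %.3g)\n",
              object@ic50UM, object@h, object@residualSD))
})

#' @describeIn BoostParams-class compact display
#' @param object object to display
#' @export
setMethod("show", "BoostParams", function(object) {
  cat(sprintf("BoostParams (%s bound): E = %.4g, k = %.4g [%s]\n",
              object@bound, object@E, object@k, object@unit))
})

#' @describeIn LIEResult-class compact display
#' @param object object to display
#' @export
setMethod("show", "LIEResult", function(object) {
  cat(sprintf(
    "LIEResult: dE_Q = %.2f, dE_vdW = %.2f, dF = %.2f kJ/mol\n",
    object@dEQ, object@dEvdW, object@dF))
})

#' @describeIn StateMap-class compact display
#' @param object object to display
#' @export
setMethod("show", "StateMap", function(object) {
  cat("StateMap with", length(object@labels), "states\n")
  for (i in seq_along(object@labels))
    cat(sprintf("  %-4s center (%.2f, %.2f) A  population %d\n",
                object@labels[i], object@centers[i, 1],
                object@centers[i, 2], object@populations[i]))
})

#' @describeIn CalibCurve-class compact display
#' @param object object to display
#' @export
setMethod("show", "CalibCurve", function(object) {
  cat(sprintf(
    "CalibCurve: pH %g-%g, midpoint ratio %.3g, slope %.3g (ratio %.3g-%.3g)\n",
    object@pHmin, object@pHmax, object@ratioHalf, object@slope,
    object@ratioRange[1], object@ratioRange[2]))
})
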