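#' Convert a voltage-ramp trace to an I-V curve
#'
#' Maps each sample time to the instantaneous command voltage of the ramp
#' protocol and averages repeated ramps sample-wise. The returned curve is
#' ordered by ascending voltage.
#'
#' @param trace a [TraceRecord-class]; its duration must be an integer
#'   number of ramp repetitions.
#' @param protocol a ramp [VoltageProtocol-class] (see [rampProtocol()]).
#' @return Data frame with columns `voltage_mV`, `i_pA`.
#' @examples
#' pr <- rampProtocol(100, -150, 1000, samplingKHz = 1)
#' v <- seq(100, -150, length.out = 1000)
#' tr <- traceRecord(v * 1.0, samplingKHz = 1)  # 1 nS Ohmic cell
#' iv <- rampToIV(tr, pr)
#' @export
rampToIV <- function(trace, protocol) {
  stopifnot(is(trace, "TraceRecord"), is(protocol, "VoltageProtocol"))
  if (protocol@kind != "ramp") stop("a ramp protocol is required")
  nPerRamp <- round(protocol@rampMS * trace@samplingKHz)
  n <- length(trace@iPA)
  if (n < nPerRamp)
    stop("trace shorter than one ramp (", n, " < ", nPerRamp, " samples)")
  nRamps <- n %/% nPerRamp
  if (n %% nPerRamp != 0)
    stop("trace length is not a whole number of ramps")
  i <- matrix(trace@iPA[seq_len(nRamps * nPerRamp)], nrow = nPerRamp)
  iMean <- rowMeans(i)
  v <- seq(protocol@rampFromMV, protocol@rampToMV, length.out = nPerRamp)
  o <- order(v)
  data.frame(voltage_mV = v[o], i_pA = iMean[o])
}

#' Reversal potential of an I-V curve
#'
#' Linear interpolation between the samples bracketing the zero-current
#' crossing. When several crossings exist the one nearest 0 mV is used and
#' a warning is emitted.
#'
#' @param iv data frame with columns `voltage_mV` (strictly monotone) and
#'   `i_pA`.
#' @return Reversal potential in mV.
#' @examples
#' iv <- data.frame(voltage_mV = -20:20, i_pA = 2 * (-20:20 + 7.7))
#' reversalPotential(iv)  # -7.7
#' @export
reversalPotential <- function(iv) {
  stopifnot(all(c("voltage_mV", "i_pA") %in% names(iv)))
  v <- iv$voltage_mV
  i <- iv$i_pA
  exact <- which(i == 0)
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] < 0)
  erevs <- c(
    v[exact],
    vapply(cross, function(j)
      v[j] - i[j] * (v[j + 1] - v[j]) / (i[j + 1] - i[j]), numeric(1)))
  if (!length(erevs))
    stop("no zero-current crossing in the voltage range")
  erevs <- unique(erevs)
  if (length(erevs) > 1L)
    warning("multiple zero crossings; returning the one nearest 0 mV")
  erevs[which.min(abs(erevs))]
}

#' Bi-ionic Goldman-Hodgkin-Katz permeability ratio
#'
#' Under the equimolar bi-ionic substitution design (the 150 mM external
#' Na+ replaced by 150 mM of test cation X with the internal solution
#' fixed), the GHK relation reduces to
#' `P_X/P_Na = exp(F * (Erev_X - Erev_Na) / (R*T))`.
#'
#' @param erevNaMV reversal potential with Na+ in the bath (mV).
#' @param erevXMV reversal potential with the test cation in the bath (mV).
#' @param temperatureK absolute temperature (default 298.15 K, room
#'   temperature).
#' @return A list with `ratio` (P_X/P_Na), `deltaErevMV` and
#'   `temperatureK`.
#' @examples
#' ghkPermeabilityRatio(-7.7, 0.5)$ratio  # ~1.4 for K+ vs Na+
#' @export
ghkPermeabilityRatio <- function(erevNaMV, erevXMV,
                                 temperatureK = 298.15) {
  dE <- erevXMV - erevNaMV
  ratio <- exp(dE / rtOverF(temperatureK))
  list(ratio = ratio, deltaErevMV = dE, temperatureK = temperatureK)
}

#' @rdname ghkPermeabilityRatio
#' @description `ghkDeltaErev()` is the inverse map: the reversal-potential
#' shift predicted from a permeability ratio.
#' @param ratio permeability ratio P_X/P_Na (> 0).
#' @return `ghkDeltaErev()`: the predicted `Erev_X - Erev_Na` in mV.
#' @export
ghkDeltaErev <- function(ratio, temperatureK = 298.15) {
  stopifnot(ratio > 0)
  rtOverF(temperatureK) * log(ratio)
}

#' Full two-term GHK permeability ratio from complete solution data
#'
#' For users supplying complete external compositions for the two bath
#' conditions and the (fixed) internal composition, solves the two-term
#' GHK reversal-potential difference
#' \deqn{\Delta E_{rev} = \frac{RT}{F}\ln\frac{P_{Na}[Na]_{o,Na} +
#'   P_X[X]_{o,Na}}{P_{Na}[Na]_i + P_X[X]_i} - \frac{RT}{F}
#'   \ln\frac{P_{Na}[Na]_{o,X} + P_X[X]_{o,X}}{P_{Na}[Na]_i + P_X[X]_i}}
#' for the ratio `P_X/P_Na` numerically.
#'
#' @param deltaErevMV measured `Erev_X - Erev_Na` in mV.
#' @param naBath,xBath named numeric `c(Na = , X = )` external
#'   concentrations (mM) in the Na+ and test-cation conditions.
#' @param internal named numeric `c(Na = , X = )` internal concentrations
#'   (mM), identical across conditions.
#' @param temperatureK absolute temperature in K.
#' @return The permeability ratio P_X/P_Na.
#' @export
ghkPermeabilityRatioFull <- function(deltaErevMV,
                                     naBath = c(Na = 150, X = 0),
                                     xBath = c(Na = 0, X = 150),
                                     internal = c(Na = 0, X = 140),
                                     temperatureK = 298.15) {
  rtf <- rtOverF(temperatureK)
  predicted <- function(r) {
    t1 <- log((naBath[["Na"]] + r * naBath[["X"]]) /
                (internal[["Na"]] + r * internal[["X"]]))
    t2 <- log((xBath[["Na"]] + r * xBath[["X"]]) /
                (internal[["Na"]] + r * internal[["X"]]))
    rtf * (t1 - t2)
  }
  # deltaErev as defined above is Erev_Na - Erev_X; flip to match input
  f <- function(r) -predicted(r) - deltaErevMV
  stats::uniroot(f, c(1e-6, 1e6), tol = 1e-12)$root
}

#' Fit the Hill inhibition model to dose-response data
#'
#' Nonlinear least squares of `Y = 100 / (1 + (IC50/X)^h)` with a
#' multi-start strategy (geometric IC50 grid over the concentration range
#' crossed with positive and negative slope starts). The Hill slope keeps
#' its sign: negative slopes describe inhibition under this convention.
#'
#' @param data a [DoseResponse-class], or a data frame with columns
#'   `concentrationUM` and `responsePct`.
#' @param init optional named start values `c(ic50 = , h = )`.
#' @return A [HillFit-class].
#' @examples
#' dr <- genDoseResponse(0.10, -1.301, c(0.01, 0.03, 0.1, 1, 10))
#' hillFit(dr)
#' @export
hillFit <- function(data, init = NULL) {
  if (is(data, "DoseResponse")) {
    x <- data@concentrationUM
    y <- data@responsePct
  } else {
    x <- data$concentrationUM
    y <- data$responsePct
  }
  if (length(unique(x)) < 3L)
    stop("at least 3 distinct concentrations are required")

  df <- data.frame(x = x, y = y)
  starts <- if (!is.null(init)) {
    list(list(ic50 = unname(init[["ic50"]]), h = unname(init[["h"]])))
  } else {
    ic50Grid <- exp(seq(log(min(x)), log(max(x)), length.out = 5))
    hGrid <- c(-2, -1, -0.5, 0.5, 1, 2)
    unlist(lapply(ic50Grid, function(a)
      lapply(hGrid, function(b) list(ic50 = a, h = b))), recursive = FALSE)
  }

  best <- NULL
  tried <- character()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 100 / (1 + (ic50 / x)^h), data = df,
                        start = st, lower = c(ic50 = 1e-12, h = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        tried <<- c(tried, conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("Hill fit failed to converge from every start; messages: ",
         paste(unique(tried), collapse = " | "))

  cf <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit),
                 error = function(e) matrix(NA_real_, 2, 2))
  new("HillFit", ic50UM = unname(cf[["ic50"]]), h = unname(cf[["h"]]),
      vcov = vc, residualSD = stats::sigma(best$fit))
}

#' Normalize a current series to a reference pH
#'
#' @param currents currents (pA or pA/pF), one per pH level.
#' @param pH pH values matching `currents`.
#' @param refPH reference pH (must be present; its current must be
#'   nonzero).
#' @return Data frame `pH`, `normalized` with the reference mapping to 1.
#' @examples
#' normalizePhSeries(c(-320, -300, -150), c(8.0, 7.3, 6.0))
#' @export
normalizePhSeries <- function(currents, pH, refPH = 7.3) {
  stopifnot(length(currents) == length(pH))
  j <- which(pH == refPH)
  if (!length(j)) stop("reference pH ", refPH, " not present")
  ref <- currents[j[1]]
  if (ref == 0) stop("reference current is zero; cannot normalize")
  data.frame(pH = pH, normalized = currents / ref)
}
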