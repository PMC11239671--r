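#' Construct a gating model
#'
#' @param stateLabels character labels (from `closed`, `open`, `sub`,
#'   optionally suffixed).
#' @param conductancePS per-state conductance in pS (closed states 0).
#' @param rates function of holding potential (mV) returning the
#'   transition-rate matrix (1/ms), or a single rate matrix used at all
#'   voltages.
#' @param erevMV reversal potential of the unitary current (mV).
#' @return A [GatingModel-class] object.
#' @examples
#' Q <- matrix(c(-1/41, 1/41, 1/26, -1/26), 2, byrow = TRUE)
#' m <- gatingModel(c("closed", "open"), c(0, 60), Q, erevMV = 0)
#' @export
gatingModel <- function(stateLabels, conductancePS, rates, erevMV = 0) {
  if (is.matrix(rates)) {
    Q <- rates
    rates <- function(voltage_mV) Q
  }
  checkRateMatrix(rates(0), length(stateLabels))
  new("GatingModel", stateLabels = stateLabels,
      conductancePS = as.numeric(conductancePS), rates = rates,
      erevMV = as.numeric(erevMV))
}

checkRateMatrix <- function(Q, n) {
  if (!is.matrix(Q) || nrow(Q) != n || ncol(Q) != n)
    stop("rate matrix must be ", n, " x ", n)
  off <- Q
  diag(off) <- 0
  if (any(off < 0))
    stop("off-diagonal transition rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-9 * pmax(1, abs(diag(Q)))))
    stop("each diagonal entry must equal minus its row's off-diagonal sum")
  invisible(Q)
}

#' Two-state closed/open gating model
#'
#' Convenience constructor for a closed <-> open model specified either by
#' the mean dwell times or by a target stationary open probability. With
#' both `tauOpenMS` and `tauClosedMS` given, the stationary open fraction
#' is `tauOpen/(tauOpen + tauClosed)`; with `po` given, the closed dwell is
#' adjusted so the stationary open fraction equals `po` while the open
#' dwell stays at `tauOpenMS`.
#'
#' @param tauOpenMS mean open dwell (ms).
#' @param tauClosedMS mean closed dwell (ms); ignored when `po` is given.
#' @param po optional target stationary open probability in (0, 1).
#' @param conductancePS open-state conductance (pS).
#' @param erevMV reversal potential (mV).
#' @return A [GatingModel-class] with states `closed`, `open`.
#' @examples
#' twoStateGatingModel(tauOpenMS = 26, tauClosedMS = 41)
#' twoStateGatingModel(tauOpenMS = 26, po = 0.6)
#' @export
twoStateGatingModel <- function(tauOpenMS, tauClosedMS = NULL, po = NULL,
                                conductancePS = 60, erevMV = 0) {
  stopifnot(tauOpenMS > 0)
  if (!is.null(po)) {
    stopifnot(po > 0, po < 1)
    tauClosedMS <- tauOpenMS * (1 - po) / po
  }
  stopifnot(!is.null(tauClosedMS), tauClosedMS > 0)
  alpha <- 1 / tauClosedMS  # opening rate, 1/ms
  beta <- 1 / tauOpenMS     # closing rate, 1/ms
  Q <- matrix(c(-alpha, alpha, beta, -beta), 2, 2, byrow = TRUE)
  gatingModel(c("closed", "open"), c(0, conductancePS), Q, erevMV)
}

#' Default voltage-dependent gating model
#'
#' The package's default model of GolpHCat gating: a U-shaped
#' voltage-dependent open probability centered on 0 mV, anchored to the
#' measured dwell kinetics (mean open/closed 26/41 ms at +90 mV and
#' 421/505 ms at -150 mV) with the opening rate scaled linearly to zero at
#' 0 mV, so no openings occur at the resting potential. At positive
#' voltages a half-conductance subconductance level is reachable from the
#' open state; no subconductance kinetics have been published, so those
#' rates are exposed as arguments.
#'
#' @param conductancePS full open-state conductance in pS.
#' @param erevMV unitary-current reversal potential in mV.
#' @param subOnRate,subOffRate open -> sub and sub -> open rates (1/ms)
#'   applied at positive voltages only.
#' @return A [GatingModel-class] with states `closed`, `open`, `sub`.
#' @examples
#' m <- defaultGatingModel()
#' m@rates(90)
#' m@rates(0)   # opening rate 0: the chain is absorbed in 'closed'
#' @export
defaultGatingModel <- function(conductancePS = 60, erevMV = 0,
                               subOnRate = 0.02, subOffRate = 0.1) {
  rates <- function(voltage_mV) {
    v <- voltage_mV
    if (v >= 0) {
      alpha <- (v / 90) * (1 / 41)
      beta <- 1 / 26
      kos <- if (v > 0) subOnRate else 0
      kso <- if (v > 0) subOffRate else 0
    } else {
      alpha <- (-v / 150) * (1 / 505)
      beta <- 1 / 421
      kos <- 0
      kso <- 0
    }
    Q <- matrix(0, 3, 3)
    Q[1, 2] <- alpha
    Q[2, 1] <- beta
    Q[2, 3] <- kos
    Q[3, 2] <- kso
    diag(Q) <- -rowSums(Q)
    Q
  }
  gatingModel(c("closed", "open", "sub"),
              c(0, conductancePS, conductancePS / 2), rates, erevMV)
}

#' Step and ramp voltage protocols
#'
#' `stepProtocol()` defaults to the +90 to -150 mV, 30 mV-step family used
#' for single-channel recordings; `rampProtocol()` defaults to the
#' 1000-ms whole-cell ramp descending from +100 to -150 mV.
#'
#' @param levelsMV step levels in mV.
#' @param durationsMS per-level durations in ms (recycled).
#' @param samplingKHz sampling rate in kHz.
#' @return A [VoltageProtocol-class] object.
#' @examples
#' stepProtocol()
#' rampProtocol()
#' @export
stepProtocol <- function(levelsMV = seq(90, -150, by = -30),
                         durationsMS = 1000, samplingKHz = 10) {
  new("VoltageProtocol", kind = "step", levelsMV = levelsMV,
      durationsMS = rep_len(durationsMS, length(levelsMV)),
      rampFromMV = NA_real_, rampToMV = NA_real_, rampMS = NA_real_,
      samplingKHz = samplingKHz)
}

#' @rdname stepProtocol
#' @param fromMV,toMV ramp start and end potentials in mV.
#' @param rampMS ramp duration in ms.
#' @export
rampProtocol <- function(fromMV = 100, toMV = -150, rampMS = 1000,
                         samplingKHz = 10) {
  new("VoltageProtocol", kind = "ramp", levelsMV = numeric(),
      durationsMS = numeric(), rampFromMV = fromMV, rampToMV = toMV,
      rampMS = rampMS, samplingKHz = samplingKHz)
}

#' Construct an event sequence
#'
#' Merges adjacent equal-state events so the alternating-state invariant
#' holds.
#'
#' @param states character state labels.
#' @param durationsMS positive dwell durations (ms).
#' @return An [EventSequence-class] object.
#' @export
eventSequence <- function(states, durationsMS) {
  stopifnot(length(states) == length(durationsMS))
  keep <- durationsMS > 0
  states <- states[keep]
  durationsMS <- durationsMS[keep]
  if (length(states) > 1L) {
    grp <- cumsum(c(TRUE, states[-1L] != states[-length(states)]))
    durationsMS <- as.numeric(tapply(durationsMS, grp, sum))
    states <- states[!duplicated(grp)]
  }
  new("EventSequence", states = states, durationsMS = durationsMS,
      totalMS = sum(durationsMS))
}

#' Construct a trace record
#'
#' @param iPA current samples in pA.
#' @param samplingKHz sampling rate in kHz.
#' @param holdingMV holding potential in mV.
#' @param filterKHz optional low-pass cutoff (kHz).
#' @param meta named metadata list.
#' @param tMS optional explicit time base; defaults to a uniform grid.
#' @return A [TraceRecord-class] object.
#' @export
traceRecord <- function(iPA, samplingKHz, holdingMV = NA_real_,
                        filterKHz = NA_real_, meta = list(), tMS = NULL) {
  if (is.null(tMS))
    tMS <- seq_along(iPA) / samplingKHz - 1 / samplingKHz
  new("TraceRecord", tMS = tMS, iPA = iPA, holdingMV = holdingMV,
      samplingKHz = samplingKHz, filterKHz = filterKHz, meta = meta)
}

#' Construct a solution specification
#'
#' @param ions named concentrations in mM.
#' @param pH solution pH.
#' @param role `"pipette"` or `"bath"`.
#' @return A [SolutionSpec-class] object.
#' @examples
#' bath <- solutionSpec(c(Na = 152, K = 3, Cl = 158, Mg = 2, Ca = 2),
#'                      pH = 7.3, role = "bath")
#' @export
solutionSpec <- function(ions, pH = 7.3, role = c("bath", "pipette")) {
  new("SolutionSpec", ions = ions, pH = pH, role = match.arg(role))
}

#' Construct a coordinate frame
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param masses per-atom masses; defaults to 1 for all atoms.
#' @param tags named list of integer index vectors (`tmd`, `phosphorus`,
#'   `r2_chain`, ...).
#' @return A [CoordinateFrame-class] object.
#' @export
coordinateFrame <- function(xyz, masses = rep(1, nrow(xyz)), tags = list()) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  new("CoordinateFrame", xyz = xyz, masses = as.numeric(masses), tags = tags)
}

#' Construct a Boltzmann pH calibration curve
#'
#' @param pHmin,pHmax lower and upper pH asymptotes.
#' @param ratioHalf midpoint 405:475 ratio.
#' @param slope sigmoid slope in ratio units.
#' @param ratioRange valid ratio range; defaults to the central 98% of the
#'   sigmoid (where the inverse is numerically stable).
#' @return A [CalibCurve-class] object.
#' @examples
#' cal <- boltzmannCalib(pHmin = 5, pHmax = 9, ratioHalf = 1, slope = 0.3)
#' ratioToPH(calibInverse(cal, 6.3), cal)
#' @export
boltzmannCalib <- function(pHmin = 5, pHmax = 9, ratioHalf = 1, slope = 0.3,
                           ratioRange = NULL) {
  if (is.null(ratioRange)) {
    # ratio at which the sigmoid reaches 1% / 99% of its span
    span <- log(99)
    ratioRange <- sort(ratioHalf + c(-1, 1) * span * abs(slope))
  }
  new("CalibCurve", pHmin = pHmin, pHmax = pHmax, ratioHalf = ratioHalf,
      slope = slope, residualSD = 0, ratioRange = ratioRange)
}
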