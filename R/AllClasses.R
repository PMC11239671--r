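#' @import methods
NULL

#' GatingModel: a continuous-time Markov model of single-channel gating
#'
#' A gating model is a finite-state continuous-time Markov chain whose
#' states carry a conductance. The transition-rate matrix may depend on the
#' holding potential, which is how the channel's U-shaped voltage-dependent
#' open probability (zero at 0 mV, rising at both polarities) is encoded.
#'
#' @slot stateLabels character vector of state labels; each must be one of
#'   `"closed"`, `"open"` or `"sub"` optionally followed by a suffix
#'   (e.g. `"open2"`).
#' @slot conductancePS numeric per-state conductance in pS; closed states
#'   must have exactly 0.
#' @slot rates a function `function(voltage_mV)` returning the
#'   transition-rate matrix in 1/ms between states (off-diagonal entries
#'   are non-negative; each diagonal entry equals minus its row sum).
#' @slot erevMV reversal potential of the unitary current in mV.
#'
#' @seealso [gatingModel()], [twoStateGatingModel()], [defaultGatingModel()]
#' @export
setClass("GatingModel",
  representation(
    stateLabels = "character",
    conductancePS = "numeric",
    rates = "function",
    erevMV = "numeric"
  )
)

setValidity("GatingModel", function(object) {
  msg <- character()
  n <- length(object@stateLabels)
  if (n < 1L) msg <- c(msg, "at least one state is required")
  base <- sub("[0-9]*$", "", object@stateLabels)
  if (!all(base %in% c("closed", "open", "sub")))
    msg <- c(msg, "state labels must derive from 'closed', 'open' or 'sub'")
  if (length(object@conductancePS) != n)
    msg <- c(msg, "conductancePS must have one entry per state")
  closedIdx <- base == "closed"
  if (any(object@conductancePS[closedIdx] != 0))
    msg <- c(msg, "closed-state conductance must be exactly 0")
  if (any(object@conductancePS < 0))
    msg <- c(msg, "conductances must be non-negative")
  if (length(object@erevMV) != 1L || !is.finite(object@erevMV))
    msg <- c(msg, "erevMV must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' VoltageProtocol: a step or ramp voltage-command protocol
#'
#' @slot kind `"step"` or `"ramp"`.
#' @slot levelsMV ordered command levels (mV) for a step protocol.
#' @slot durationsMS per-level duration (ms) for a step protocol.
#' @slot rampFromMV,rampToMV,rampMS ramp start, end (mV) and duration (ms).
#' @slot samplingKHz sampling rate in kHz.
#'
#' @seealso [stepProtocol()], [rampProtocol()]
#' @export
setClass("VoltageProtocol",
  representation(
    kind = "character",
    levelsMV = "numeric",
    durationsMS = "numeric",
    rampFromMV = "numeric",
    rampToMV = "numeric",
    rampMS = "numeric",
    samplingKHz = "numeric"
  )
)

setValidity("VoltageProtocol", function(object) {
  msg <- character()
  if (!object@kind %in% c("step", "ramp"))
    msg <- c(msg, "kind must be 'step' or 'ramp'")
  if (length(object@samplingKHz) != 1L || object@samplingKHz <= 0)
    msg <- c(msg, "samplingKHz must be a single positive number")
  if (object@kind == "step") {
    if (length(object@levelsMV) < 1L)
      msg <- c(msg, "a step protocol needs at least one level")
    if (length(object@durationsMS) != length(object@levelsMV))
      msg <- c(msg, "durationsMS must match levelsMV in length")
    if (any(object@durationsMS <= 0))
      msg <- c(msg, "durations must be positive")
  } else {
    if (length(object@rampMS) != 1L || object@rampMS <= 0)
      msg <- c(msg, "rampMS must be a single positive duration")
  }
  if (length(msg)) msg else TRUE
})

#' EventSequence: an idealized single-channel record
#'
#' Ordered (state, duration) pairs, the idealized representation of a
#' single-channel current trace. Adjacent events always carry distinct
#' states and durations are positive.
#'
#' @slot states character vector of state labels, one per event.
#' @slot durationsMS positive dwell durations in ms.
#' @slot totalMS total duration (sum of dwells).
#'
#' @seealso [simulateGating()], [idealize()], [openProbability()]
#' @export
setClass("EventSequence",
  representation(
    states = "character",
    durationsMS = "numeric",
    totalMS = "numeric"
  )
)

setValidity("EventSequence", function(object) {
  msg <- character()
  n <- length(object@states)
  if (length(object@durationsMS) != n)
    msg <- c(msg, "states and durationsMS must have equal length")
  if (n > 0L && any(object@durationsMS <= 0))
    msg <- c(msg, "all durations must be positive")
  if (n > 1L && any(object@states[-1L] == object@states[-n]))
    msg <- c(msg, "adjacent events must have distinct states")
  if (n > 0L &&
      abs(sum(object@durationsMS) - object@totalMS) >
        max(1e-6, 1e-9 * object@totalMS))
    msg <- c(msg, "durations must sum to totalMS")
  if (length(msg)) msg else TRUE
})

#' TraceRecord: a sampled current trace
#'
#' @slot tMS uniformly spaced time base in ms.
#' @slot iPA current samples in pA (inward current negative).
#' @slot holdingMV holding potential in mV.
#' @slot samplingKHz sampling rate in kHz.
#' @slot filterKHz low-pass cutoff in kHz (`NA_real_` when unfiltered).
#' @slot meta named list of provenance metadata (seed, model id, ...).
#'
#' @seealso [renderTrace()], [readTraceCSV()], [writeTraceCSV()]
#' @export
setClass("TraceRecord",
  representation(
    tMS = "numeric",
    iPA = "numeric",
    holdingMV = "numeric",
    samplingKHz = "numeric",
    filterKHz = "numeric",
    meta = "list"
  ),
  prototype(filterKHz = NA_real_, meta = list())
)

setValidity("TraceRecord", function(object) {
  msg <- character()
  if (length(object@tMS) != length(object@iPA))
    msg <- c(msg, "tMS and iPA must have equal length")
  if (length(object@samplingKHz) != 1L || object@samplingKHz <= 0)
    msg <- c(msg, "samplingKHz must be a single positive number")
  if (length(object@tMS) > 1L) {
    dt <- diff(object@tMS)
    expected <- 1 / object@samplingKHz
    if (any(dt <= 0) || any(abs(dt - expected) > 1e-6 * expected))
      msg <- c(msg,
        "tMS must be strictly increasing with uniform spacing 1/samplingKHz")
  }
  if (length(msg)) msg else TRUE
})

#' DoseResponse: inhibitor concentrations and percentage currents
#'
#' @slot concentrationUM tested concentrations in µM (one per observation).
#' @slot responsePct percentage current (% of control).
#' @slot replicate integer replicate id per observation.
#' @slot meta named list with generator ground truth where applicable.
#'
#' @seealso [genDoseResponse()], [hillFit()]
#' @export
setClass("DoseResponse",
  representation(
    concentrationUM = "numeric",
    responsePct = "numeric",
    replicate = "integer",
    meta = "list"
  ),
  prototype(meta = list())
)

setValidity("DoseResponse", function(object) {
  msg <- character()
  n <- length(object@concentrationUM)
  if (length(object@responsePct) != n || length(object@replicate) != n)
    msg <- c(msg, "concentrationUM, responsePct and replicate lengths differ")
  if (any(object@concentrationUM <= 0))
    msg <- c(msg, "concentrations must be positive")
  if (length(msg)) msg else TRUE
})

#' FluorTraces: two-channel ratiometric fluorescence time series
#'
#' Per-timepoint intensities of the 405 nm- and 475 nm-excited channels of
#' a ratiometric pH sensor, plus the stimulus onset time.
#'
#' @slot tS time base in seconds.
#' @slot f405,f475 channel intensities (arbitrary units, positive).
#' @slot stimulusOnsetS onset of the NH4Cl (or other) stimulus in seconds.
#' @slot meta named list of provenance metadata.
#'
#' @seealso [genPhTraces()], [ratioSeries()]
#' @export
setClass("FluorTraces",
  representation(
    tS = "numeric",
    f405 = "numeric",
    f475 = "numeric",
    stimulusOnsetS = "numeric",
    meta = "list"
  ),
  prototype(meta = list())
)

setValidity("FluorTraces", function(object) {
  msg <- character()
  n <- length(object@tS)
  if (length(object@f405) != n || length(object@f475) != n)
    msg <- c(msg, "tS, f405 and f475 must have equal length")
  if (n > 0L && (any(object@f405 <= 0) || any(object@f475 <= 0)))
    msg <- c(msg, "intensities must be positive")
  if (length(msg)) msg else TRUE
})

#' DwellFit: maximum-likelihood single-exponential dwell-time fit
#'
#' @slot tauMS fitted time constant in ms.
#' @slot nEvents number of dwells used.
#' @slot logLik log-likelihood at the MLE.
#' @slot deadTimeMS left-truncation dead time in ms.
#' @export
setClass("DwellFit",
  representation(
    tauMS = "numeric",
    nEvents = "integer",
    logLik = "numeric",
    deadTimeMS = "numeric"
  )
)

#' AmpHistFit: Gaussian-mixture fit of a current-amplitude distribution
#'
#' @slot means component means in pA, sorted ascending.
#' @slot sds component standard deviations in pA.
#' @slot weights mixing weights (non-negative, summing to 1).
#' @slot breaks,counts histogram bin edges and counts (for plotting).
#' @slot separation peak separation / pooled SD quality metric.
#' @slot logLik mixture log-likelihood.
#' @export
setClass("AmpHistFit",
  representation(
    means = "numeric",
    sds = "numeric",
    weights = "numeric",
    breaks = "numeric",
    counts = "numeric",
    separation = "numeric",
    logLik = "numeric"
  )
)

setValidity("AmpHistFit", function(object) {
  msg <- character()
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (any(object@sds <= 0))
    msg <- c(msg, "component SDs must be positive")
  if (length(msg)) msg else TRUE
})

#' HillFit: fitted Hill inhibition curve
#'
#' Parameters of `Y = 100 / (1 + (IC50/X)^h)` fitted by nonlinear least
#' squares. The Hill slope keeps its sign (negative for inhibition under
#' the convention used here).
#'
#' @slot ic50UM half-maximal inhibitory concentration in µM.
#' @slot h signed Hill slope.
#' @slot vcov 2x2 parameter covariance matrix (ic50, h).
#' @slot residualSD residual standard deviation.
#' @seealso [hillFit()], [genDoseResponse()]
#' @export
setClass("HillFit",
  representation(
    ic50UM = "numeric",
    h = "numeric",
    vcov = "matrix",
    residualSD = "numeric"
  )
)

setValidity("HillFit", function(object) {
  if (object@ic50UM <= 0) "ic50UM must be positive" else TRUE
})

#' SolutionSpec: ionic composition of a pipette or bath solution
#'
#' @slot ions named numeric vector of concentrations in mM (names are ion
#'   identifiers matching the mobility table, e.g. `"Na"`, `"K"`,
#'   `"Cl"`, `"gluconate"`).
#' @slot pH solution pH.
#' @slot role `"pipette"` or `"bath"` (informational).
#' @seealso [solutionSpec()], [hendersonLJP()]
#' @export
setClass("SolutionSpec",
  representation(ions = "numeric", pH = "numeric", role = "character")
)

setValidity("SolutionSpec", function(object) {
  msg <- character()
  if (is.null(names(object@ions)) || any(!nzchar(names(object@ions))))
    msg <- c(msg, "ions must be a named vector")
  if (any(object@ions < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' BoostParams: parameters of the harmonic boost potential
#'
#' Reference energy E and force constant k of the Gaussian-accelerated
#' boost, which must satisfy `Vmax <= E <= Vmin + 1/k`.
#'
#' @slot E reference energy.
#' @slot k harmonic force constant (1/energy).
#' @slot sigma0 upper limit of the boost standard deviation.
#' @slot bound `"lower"` or `"upper"` reference-energy bound choice.
#' @slot unit `"kcal/mol"` or `"kJ/mol"` energy unit tag.
#' @seealso [selectBoostParams()], [boostPotential()]
#' @export
setClass("BoostParams",
  representation(
    E = "numeric", k = "numeric", sigma0 = "numeric",
    bound = "character", unit = "character"
  ),
  prototype(bound = "upper", unit = "kcal/mol")
)

setValidity("BoostParams", function(object) {
  msg <- character()
  if (object@k <= 0) msg <- c(msg, "k must be positive")
  if (!object@bound %in% c("lower", "upper"))
    msg <- c(msg, "bound must be 'lower' or 'upper'")
  if (!object@unit %in% c("kcal/mol", "kJ/mol"))
    msg <- c(msg, "unit must be 'kcal/mol' or 'kJ/mol'")
  if (length(msg)) msg else TRUE
})

#' EnergyComponents: averaged interaction energies for the LIE estimator
#'
#' Average coulombic and van der Waals interaction energies for the five
#' subsystems entering the linear-interaction-energy thermodynamic cycle:
#' the protein-lipid complex (`p-L`), the bare protein (`p*`), the lipid
#' in vacuum/gas reference (`L(g)`), the membrane-lipid system (`m-L`) and
#' the bare membrane (`m*`).
#'
#' @slot energies named list with entries `"p-L"`, `"p*"`, `"L(g)"`,
#'   `"m-L"`, `"m*"`; each a numeric vector `c(Q = , vdW = )` in kJ/mol.
#' @slot burnInDiscarded number of leading frames discarded per series.
#' @seealso [energyComponents()], [lieFreeEnergy()]
#' @export
setClass("EnergyComponents",
  representation(energies = "list", burnInDiscarded = "integer"),
  prototype(burnInDiscarded = 0L)
)

lieSubsystems <- c("p-L", "p*", "L(g)", "m-L", "m*")

setValidity("EnergyComponents", function(object) {
  msg <- character()
  missing <- setdiff(lieSubsystems, names(object@energies))
  if (length(missing))
    msg <- c(msg, paste0("missing subsystem(s): ",
                         paste(missing, collapse = ", ")))
  ok <- vapply(object@energies, function(e)
    is.numeric(e) && all(c("Q", "vdW") %in% names(e)), logical(1))
  if (!all(ok))
    msg <- c(msg, "each subsystem needs named entries Q and vdW")
  if (length(msg)) msg else TRUE
})

#' LIEResult: linear-interaction-energy binding free energy
#'
#' @slot dEQ coulombic interaction-energy change for the membrane-to-protein
#'   transfer, kJ/mol.
#' @slot dEvdW van der Waals interaction-energy change, kJ/mol.
#' @slot dF estimated binding free energy `0.5*dEQ + 0.16*dEvdW`, kJ/mol.
#' @seealso [lieFreeEnergy()]
#' @export
setClass("LIEResult",
  representation(dEQ = "numeric", dEvdW = "numeric", dF = "numeric")
)

setValidity("LIEResult", function(object) {
  if (abs(object@dF - (0.5 * object@dEQ + 0.16 * object@dEvdW)) > 1e-9)
    "dF must equal 0.5*dEQ + 0.16*dEvdW exactly" else TRUE
})

#' CoordinateFrame: a single frame of atomic coordinates
#'
#' @slot xyz n x 3 matrix of coordinates in Angstrom.
#' @slot masses per-atom masses (amu).
#' @slot tags named list of integer index vectors; recognised tags are
#'   `tmd` (transmembrane-domain atoms defining the principal axis),
#'   `phosphorus` (the lipid phosphorus atom) and `r2_chain` (the
#'   R2-fatty-acid-chain atoms).
#' @seealso [coordinateFrame()], [readPDBFrame()], [axisDistances()]
#' @export
setClass("CoordinateFrame",
  representation(xyz = "matrix", masses = "numeric", tags = "list"),
  prototype(tags = list())
)

setValidity("CoordinateFrame", function(object) {
  msg <- character()
  if (ncol(object@xyz) != 3L) msg <- c(msg, "xyz must have three columns")
  if (!all(is.finite(object@xyz))) msg <- c(msg, "coordinates must be finite")
  if (length(object@masses) != nrow(object@xyz))
    msg <- c(msg, "masses must have one entry per atom")
  if (any(object@masses <= 0)) msg <- c(msg, "masses must be positive")
  n <- nrow(object@xyz)
  for (tag in names(object@tags)) {
    idx <- object@tags[[tag]]
    if (length(idx) && (any(idx < 1L) || any(idx > n)))
      msg <- c(msg, paste0("tag '", tag, "' indexes out of range"))
  }
  if (length(msg)) msg else TRUE
})

#' Axis: a line in 3-D given by unit direction and anchor point
#'
#' @slot direction unit direction vector (length 3).
#' @slot anchor a point on the axis in Angstrom (length 3).
#' @seealso [principalAxisSmallestMoment()], [axisDistances()]
#' @export
setClass("Axis",
  representation(direction = "numeric", anchor = "numeric")
)

setValidity("Axis", function(object) {
  msg <- character()
  if (length(object@direction) != 3L || length(object@anchor) != 3L)
    msg <- c(msg, "direction and anchor must have length 3")
  else if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    msg <- c(msg, "direction must have unit norm")
  if (length(msg)) msg else TRUE
})

#' AxisDistanceSeries: per-frame lipid-to-axis distances
#'
#' Per-frame distances of the lipid phosphorus atom (dP) and of the
#' R2-fatty-acid-chain center of mass (dR2-Cent) from the transmembrane
#' domain's smallest-moment principal axis.
#'
#' @slot dP,dR2Cent non-negative distances in Angstrom, one per frame.
#' @slot meta named list (generator ground truth where applicable).
#' @seealso [genLipidFrames()], [stateHistogram()]
#' @export
setClass("AxisDistanceSeries",
  representation(dP = "numeric", dR2Cent = "numeric", meta = "list"),
  prototype(meta = list())
)

setValidity("AxisDistanceSeries", function(object) {
  msg <- character()
  if (length(object@dP) != length(object@dR2Cent))
    msg <- c(msg, "dP and dR2Cent must have equal length")
  if (any(object@dP < 0) || any(object@dR2Cent < 0))
    msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' StateMap: 2-D histogram of lipid-binding geometry with labeled states
#'
#' @slot breaksDP,breaksDR2 histogram bin edges along dP and dR2-Cent.
#' @slot counts matrix of bin counts (rows: dP bins, cols: dR2 bins).
#' @slot centers k x 2 matrix of mode centers (dP, dR2-Cent), one row per
#'   labeled state, ordered S1 (most populated) downward.
#' @slot populations frame counts per state, strictly ordered descending.
#' @slot labels state labels `"S1"`, `"S2"`, ...
#' @seealso [stateHistogram()], [classifyFrames()]
#' @export
setClass("StateMap",
  representation(
    breaksDP = "numeric", breaksDR2 = "numeric", counts = "matrix",
    centers = "matrix", populations = "numeric", labels = "character"
  )
)

setValidity("StateMap", function(object) {
  msg <- character()
  k <- length(object@labels)
  if (nrow(object@centers) != k || length(object@populations) != k)
    msg <- c(msg, "centers, populations and labels must agree in length")
  if (k > 1L && any(diff(object@populations) > 0))
    msg <- c(msg, "populations must be ordered descending (S1 first)")
  if (length(msg)) msg else TRUE
})

#' CalibCurve: sigmoidal pH calibration of a ratiometric sensor
#'
#' Boltzmann sigmoid mapping a 405:475 fluorescence ratio to pH:
#' `pH(r) = pHmin + (pHmax - pHmin) / (1 + exp((ratioHalf - r)/slope))`,
#' monotone and invertible over its valid ratio range.
#'
#' @slot pHmin,pHmax lower and upper pH asymptotes.
#' @slot ratioHalf ratio at the sigmoid midpoint.
#' @slot slope sigmoid slope in ratio units (sign sets direction).
#' @slot residualSD residual SD of the fit (0 for analytic curves).
#' @slot ratioRange valid ratio range (length 2).
#' @seealso [boltzmannCalib()], [fitCalibration()], [ratioToPH()]
#' @export
setClass("CalibCurve",
  representation(
    pHmin = "numeric", pHmax = "numeric", ratioHalf = "numeric",
    slope = "numeric", residualSD = "numeric", ratioRange = "numeric"
  ),
  prototype(residualSD = 0)
)

setValidity("CalibCurve", function(object) {
  msg <- character()
  if (object@pHmax <= object@pHmin)
    msg <- c(msg, "pHmax must exceed pHmin")
  if (object@slope == 0) msg <- c(msg, "slope must be nonzero")
  if (length(object@ratioRange) != 2L ||
      object@ratioRange[2] <= object@ratioRange[1])
    msg <- c(msg, "ratioRange must be an increasing length-2 vector")
  if (length(msg)) msg else TRUE
})
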