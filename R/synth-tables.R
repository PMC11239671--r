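#' Generate synthetic dose-response data from the Hill model
#'
#' Noise-free responses follow `Y = 100 / (1 + (IC50/X)^h)` exactly;
#' multiplicative Gaussian noise with coefficient of variation `noiseCV`
#' is applied independently per replicate and concentration.
#'
#' @param ic50UM true IC50 in µM (> 0).
#' @param h true signed Hill slope (nonzero; negative for inhibition).
#' @param concentrationsUM tested concentrations in µM (> 0).
#' @param replicates number of replicates per concentration.
#' @param noiseCV multiplicative noise coefficient of variation (>= 0).
#' @param seed optional integer seed.
#' @return A [DoseResponse-class]; `meta` records the generating values.
#' @examples
#' # the gluconate block parameters: IC50 0.10 uM, slope -1.301
#' dr <- genDoseResponse(0.10, -1.301, c(0.01, 0.03, 0.1, 1, 10),
#'                       replicates = 5, noiseCV = 0.05, seed = 7)
#' @export
genDoseResponse <- function(ic50UM, h, concentrationsUM, replicates = 1,
                            noiseCV = 0, seed = NULL) {
  stopifnot(ic50UM > 0, all(concentrationsUM > 0), replicates >= 1,
            noiseCV >= 0)
  if (h == 0) stop("h = 0 gives a degenerate flat curve")
  x <- rep(concentrationsUM, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(concentrationsUM))
  y0 <- hillResponse(x, ic50UM, h)
  withSeed(seed, {
    y <- if (noiseCV > 0)
      y0 * (1 + stats::rnorm(length(y0), sd = noiseCV)) else y0
    new("DoseResponse", concentrationUM = x, responsePct = y,
        replicate = as.integer(rep_id),
        meta = list(ic50UM = ic50UM, h = h, noiseCV = noiseCV, seed = seed))
  })
}

# Hill inhibition curve, percentage of control current.
hillResponse <- function(x, ic50, h) 100 / (1 + (ic50 / x)^h)

#' Generate synthetic interaction-energy time series for the LIE estimator
#'
#' Independent Gaussian coulombic and van der Waals interaction-energy
#' series for each of the five LIE subsystems (`p-L`, `p*`, `L(g)`,
#' `m-L`, `m*`).
#'
#' @param meanQ,meanVdW named numeric vectors (one entry per subsystem) of
#'   mean coulombic and van der Waals energies in kJ/mol.
#' @param sd common Gaussian SD in kJ/mol (>= 0).
#' @param n number of frames per series (> 0).
#' @param seed optional integer seed.
#' @return A named list of data frames with columns `frame`, `E_Q`,
#'   `E_vdW`, one per subsystem.
#' @examples
#' subs <- c("p-L", "p*", "L(g)", "m-L", "m*")
#' tr <- genEnergyTraces(setNames(c(-60, -5, -2, -25, -3), subs),
#'                       setNames(c(-120, -10, -5, -40, -8), subs),
#'                       sd = 2, n = 500, seed = 1)
#' @export
genEnergyTraces <- function(meanQ, meanVdW, sd = 0, n = 1000, seed = NULL) {
  stopifnot(n > 0)
  if (sd < 0) stop("sd must be non-negative")
  missing <- setdiff(lieSubsystems, intersect(names(meanQ), names(meanVdW)))
  if (length(missing))
    stop("missing subsystem(s): ", paste(missing, collapse = ", "))
  withSeed(seed, {
    out <- lapply(lieSubsystems, function(s) {
      data.frame(
        frame = seq_len(n),
        E_Q = meanQ[[s]] + stats::rnorm(n, sd = sd),
        E_vdW = meanVdW[[s]] + stats::rnorm(n, sd = sd))
    })
    stats::setNames(out, lieSubsystems)
  })
}

#' Generate two-channel ratiometric fluorescence traces with an NH4Cl pulse
#'
#' The luminal pH steps by `nh4clDeltaPH` at `onsetS` (the weak-base
#' challenge); pH is mapped through the inverse calibration to a 405:475
#' ratio, which is split into two positive channels with independent
#' multiplicative Gaussian noise.
#'
#' @param restingPH resting pH before the stimulus.
#' @param calib a [CalibCurve-class]; both `restingPH` and
#'   `restingPH + nh4clDeltaPH` must lie strictly inside its pH range.
#' @param nh4clDeltaPH pH step at stimulus onset (positive for the usual
#'   alkalinization by a weak base).
#' @param onsetS stimulus onset in seconds (default 30 s).
#' @param noiseCV per-channel multiplicative noise CV (>= 0).
#' @param durationS trace duration in seconds.
#' @param hz sampling rate in Hz.
#' @param baseIntensity mean 475 nm channel intensity (arbitrary units).
#' @param seed optional integer seed.
#' @return A [FluorTraces-class]; `meta` records the ground truth.
#' @examples
#' cal <- boltzmannCalib()
#' tr <- genPhTraces(6.3, cal, nh4clDeltaPH = 0.8, seed = 3)
#' @export
genPhTraces <- function(restingPH, calib, nh4clDeltaPH = 0.8, onsetS = 30,
                        noiseCV = 0, durationS = 120, hz = 1,
                        baseIntensity = 1000, seed = NULL) {
  stopifnot(is(calib, "CalibCurve"), noiseCV >= 0, durationS > onsetS)
  tS <- seq(0, durationS, by = 1 / hz)
  ph <- ifelse(tS < onsetS, restingPH, restingPH + nh4clDeltaPH)
  ratio <- calibInverse(calib, ph)   # errors if pH outside the domain
  withSeed(seed, {
    n <- length(tS)
    noise1 <- if (noiseCV > 0) 1 + stats::rnorm(n, sd = noiseCV) else rep(1, n)
    noise2 <- if (noiseCV > 0) 1 + stats::rnorm(n, sd = noiseCV) else rep(1, n)
    f475 <- baseIntensity * noise2
    f405 <- ratio * baseIntensity * noise1
    if (any(f405 <= 0) || any(f475 <= 0))
      stop("noiseCV too large: generated intensities are not all positive")
    new("FluorTraces", tS = tS, f405 = f405, f475 = f475,
        stimulusOnsetS = onsetS,
        meta = list(restingPH = restingPH, nh4clDeltaPH = nh4clDeltaPH,
                    noiseCV = noiseCV, seed = seed))
  })
}
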