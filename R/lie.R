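#' Average interaction energies from per-frame series
#'
#' Builds the [EnergyComponents-class] for the linear-interaction-energy
#' estimator from raw per-frame coulombic and van der Waals
#' interaction-energy series, discarding a leading burn-in fraction of
#' each series before averaging (the production analysis discarded the
#' first 100 ns of 1 us trajectories, a burn-in fraction of 0.1).
#'
#' @param series named list of data frames (one per subsystem `p-L`,
#'   `p*`, `L(g)`, `m-L`, `m*`) with columns `E_Q` and `E_vdW` in kJ/mol.
#' @param burnInFrac fraction of leading frames to discard in `[0, 1)`.
#' @return An [EnergyComponents-class].
#' @seealso [genEnergyTraces()], [lieFreeEnergy()]
#' @export
energyComponents <- function(series, burnInFrac = 0.1) {
  stopifnot(burnInFrac >= 0, burnInFrac < 1)
  missing <- setdiff(lieSubsystems, names(series))
  if (length(missing))
    stop("missing subsystem(s): ", paste(missing, collapse = ", "))
  discarded <- 0L
  energies <- lapply(series[lieSubsystems], function(df) {
    stopifnot(all(c("E_Q", "E_vdW") %in% names(df)))
    n <- nrow(df)
    drop <- floor(burnInFrac * n)
    discarded <<- discarded + drop
    keep <- seq.int(drop + 1L, n)
    c(Q = mean(df$E_Q[keep]), vdW = mean(df$E_vdW[keep]))
  })
  new("EnergyComponents", energies = energies,
      burnInDiscarded = as.integer(discarded))
}

#' Linear-interaction-energy binding free energy
#'
#' From the averaged subsystem energies, the lipid-to-protein transfer
#' energies are `dE_Lp = E_{p-L} - E_{p*} - E_{L(g)}` and the
#' lipid-to-membrane energies `dE_Lm = E_{m-L} - E_{m*} - E_{L(g)}`
#' (separately for the coulombic and van der Waals terms); the
#' membrane-to-protein differences are `dE_mp = dE_Lp - dE_Lm`, and the
#' binding free energy is the weighted sum
#' `dF = 0.5 * dE_mp^Q + 0.16 * dE_mp^vdW` (kJ/mol).
#'
#' @param components an [EnergyComponents-class] (or a named list of
#'   per-frame series, forwarded to [energyComponents()]).
#' @param burnInFrac burn-in fraction when raw series are supplied.
#' @return A [LIEResult-class].
#' @examples
#' en <- list(
#'   "p-L" = c(Q = -50, vdW = -90), "p*" = c(Q = -4, vdW = -5),
#'   "L(g)" = c(Q = -1, vdW = -2), "m-L" = c(Q = -10, vdW = -15.5),
#'   "m*" = c(Q = -4, vdW = -8))
#' lieFreeEnergy(new("EnergyComponents", energies = en,
#'                   burnInDiscarded = 0L))
#' @export
lieFreeEnergy <- function(components, burnInFrac = 0.1) {
  if (!is(components, "EnergyComponents"))
    components <- energyComponents(components, burnInFrac)
  validObject(components)
  e <- components@energies
  term <- function(what) {
    dLp <- e[["p-L"]][[what]] - e[["p*"]][[what]] - e[["L(g)"]][[what]]
    dLm <- e[["m-L"]][[what]] - e[["m*"]][[what]] - e[["L(g)"]][[what]]
    dLp - dLm
  }
  dEQ <- term("Q")
  dEvdW <- term("vdW")
  new("LIEResult", dEQ = dEQ, dEvdW = dEvdW,
      dF = 0.5 * dEQ + 0.16 * dEvdW)
}
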