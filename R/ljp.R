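#' Limiting equivalent ionic conductivities
#'
#' Limiting (infinite-dilution, 25 degC) equivalent conductivities in
#' S cm^2/equiv used by the Henderson junction-potential calculation.
#' Values for the common inorganic ions follow the CRC Handbook tables;
#' the organic anions (gluconate, isethionate, HEPES, MES) and NMDG follow
#' the mobility table shipped with the JPCalc/Clampex junction-potential
#' calculator (Barry 1994).
#'
#' @return Data frame with columns `ion`, `z` (signed valence) and
#'   `lambda` (S cm^2/equiv).
#' @examples
#' ionMobilityTable()
#' @export
ionMobilityTable <- function() {
  data.frame(
    ion = c("Na", "K", "Cs", "Li", "NMDG", "H", "Mg", "Ca", "Ba",
            "Cl", "F", "Br", "I", "OH", "HCO3", "NO3",
            "gluconate", "isethionate", "aspartate", "glutamate",
            "methanesulfonate", "HEPES", "MES", "BAPTA", "EGTA", "SO4"),
    z = c(1, 1, 1, 1, 1, 1, 2, 2, 2,
          -1, -1, -1, -1, -1, -1, -1,
          -1, -1, -1, -1,
          -1, -1, -1, -4, -2, -2),
    lambda = c(50.11, 73.50, 77.26, 38.68, 25.0, 349.81, 53.06, 59.50,
               63.63,
               76.35, 55.4, 78.17, 76.84, 198.3, 44.5, 71.46,
               24.3, 26.5, 26.2, 26.0,
               48.8, 22.05, 26.8, 22.0, 24.0, 80.0),
    stringsAsFactors = FALSE)
}

#' Henderson liquid-junction potential
#'
#' Computes the junction potential between the pipette and bath solutions
#' with the Henderson equation, returned in the patch-clamp convention in
#' which the correction is added to the command potential (the corrected
#' membrane potential is `Vm = Vcmd - LJP`). With a K-gluconate-based
#' pipette against a NaCl-based bath the value is positive, near the
#' conventional +13 mV correction.
#'
#' The Henderson potential of the bath (2) relative to the pipette (1) is
#' \deqn{E_2 - E_1 = -\frac{RT}{F}\,
#'   \frac{\sum_i \mathrm{sgn}(z_i)\lambda_i\,\Delta c_i}
#'        {\sum_i |z_i|\lambda_i\,\Delta c_i}\,
#'   \ln\frac{\sum_i |z_i|\lambda_i c_{i,2}}{\sum_i |z_i|\lambda_i c_{i,1}}}
#' with \eqn{\lambda_i} the limiting equivalent conductivities and
#' \eqn{\Delta c_i = c_{i,2} - c_{i,1}} in mM. It is antisymmetric under
#' solution exchange and zero for identical solutions.
#'
#' @param pipette,bath [SolutionSpec-class] objects (or named mM vectors).
#' @param mobility mobility table as from [ionMobilityTable()].
#' @param temperatureK absolute temperature in K.
#' @return Junction potential in mV (correction to add to the command
#'   potential).
#' @examples
#' pip <- solutionSpec(c(K = 140, gluconate = 130, Cl = 10),
#'                     role = "pipette")
#' bath <- solutionSpec(c(Na = 152, K = 3, Cl = 158, Mg = 2, Ca = 2))
#' hendersonLJP(pip, bath)  # ~ +15 mV
#' @export
hendersonLJP <- function(pipette, bath, mobility = ionMobilityTable(),
                         temperatureK = 298.15) {
  ionsOf <- function(s) if (is(s, "SolutionSpec")) s@ions else s
  p <- ionsOf(pipette)
  b <- ionsOf(bath)
  ions <- union(names(p), names(b))
  missing <- setdiff(ions, mobility$ion)
  if (length(missing))
    stop("no mobility entry for ion(s): ", paste(missing, collapse = ", "))
  m <- mobility[match(ions, mobility$ion), ]
  c1 <- ifelse(ions %in% names(p), p[ions], 0)  # pipette
  c2 <- ifelse(ions %in% names(b), b[ions], 0)  # bath
  dc <- c2 - c1
  lam <- m$lambda
  z <- m$z
  num <- sum(sign(z) * lam * dc)
  den <- sum(abs(z) * lam * dc)
  g1 <- sum(abs(z) * lam * c1)
  g2 <- sum(abs(z) * lam * c2)
  if (den == 0 || g1 == 0 || g2 == 0) return(0)
  -rtOverF(temperatureK) * (num / den) * log(g2 / g1)
}
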