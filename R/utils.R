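# Run expr under a local RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Physical constants and unit conversions
#'
#' `rtOverF()` returns RT/F in mV at a given absolute temperature;
#' `kcalToKJ()` and `kjToKcal()` convert energies with the exact factor
#' 4.184.
#'
#' @param temperatureK absolute temperature in K (273-320 K accepted).
#' @return RT/F in mV, or the converted energy.
#' @examples
#' rtOverF(298.15)  # ~25.69 mV
#' kjToKcal(kcalToKJ(6))  # 6
#' @export
rtOverF <- function(temperatureK = 298.15) {
  stopifnot(temperatureK > 273, temperatureK < 320)
  R <- 8.31446261815324    # J / (mol K)
  FARADAY <- 96485.33212   # C / mol
  1000 * R * temperatureK / FARADAY
}

#' @rdname rtOverF
#' @param kcal,kj energy values to convert.
#' @export
kcalToKJ <- function(kcal) kcal * 4.184

#' @rdname rtOverF
#' @export
kjToKcal <- function(kj) kj / 4.184

#' Current density
#'
#' @param currentPA current(s) in pA.
#' @param capacitancePF membrane capacitance in pF (positive).
#' @return Current density in pA/pF.
#' @examples
#' currentDensity(300, 15)  # 20
#' @export
currentDensity <- function(currentPA, capacitancePF) {
  stopifnot(capacitancePF > 0)
  currentPA / capacitancePF
}

#' Result envelope for reproducible pipeline runs
#'
#' Wraps a stage's results with its parameters, seed and package version so
#' any run can be reproduced bit-for-bit from the envelope alone.
#'
#' @param stage stage name.
#' @param params named list of parameters (including the seed used).
#' @param results results payload (any JSON-serializable structure).
#' @param warnings character vector of warnings raised during the run.
#' @return A list with class `"resultEnvelope"`.
#' @export
resultEnvelope <- function(stage, params = list(), results = list(),
                           warnings = character()) {
  structure(list(
    stage = stage,
    version = as.character(utils::packageVersion("golphkit")),
    params = params,
    results = results,
    warnings = warnings
  ), class = "resultEnvelope")
}

#' Write a result envelope as JSON
#'
#' @param envelope a [resultEnvelope()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeResultEnvelope <- function(envelope, path) {
  jsonlite::write_json(unclass(envelope), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
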