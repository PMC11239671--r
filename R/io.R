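#' Read and write current traces as annotated CSV
#'
#' The trace format is a plain CSV with columns `t_ms,i_pA` preceded by a
#' `# key=value` header block carrying at least the sampling rate
#' (`sampling_khz`) and holding voltage (`holding_mv`); `filter_khz`,
#' `seed` and free-form metadata keys are round-tripped. Decimal parsing
#' is locale-independent (dot only). `writeTraceCSV()` followed by
#' `readTraceCSV()` is the identity.
#'
#' @param path file path.
#' @return `readTraceCSV()`: a [TraceRecord-class].
#' @examples
#' tr <- traceRecord(rnorm(100), samplingKHz = 10, holdingMV = 90)
#' f <- tempfile(fileext = ".csv")
#' writeTraceCSV(tr, f)
#' tr2 <- readTraceCSV(f)
#' @export
readTraceCSV <- function(path) {
  lines <- readLines(path)
  isHeader <- startsWith(lines, "#")
  header <- sub("^#\\s*", "", lines[isHeader])
  kv <- strsplit(header, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed header line: '", header[bad][1], "'")
  meta <- stats::setNames(
    lapply(kv, function(x) trimws(x[2])),
    vapply(kv, function(x) trimws(x[1]), character(1)))
  if (is.null(meta$sampling_khz))
    stop("missing required header key 'sampling_khz'")
  samplingKHz <- as.numeric(meta$sampling_khz)
  holdingMV <- if (!is.null(meta$holding_mv))
    as.numeric(meta$holding_mv) else NA_real_
  filterKHz <- if (!is.null(meta$filter_khz))
    as.numeric(meta$filter_khz) else NA_real_

  body <- lines[!isHeader]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L || trimws(body[1]) != "t_ms,i_pA")
    stop("expected a 't_ms,i_pA' column header after the metadata block")
  dat <- utils::read.csv(textConnection(body), colClasses = "numeric")
  extra <- meta[setdiff(names(meta),
                        c("sampling_khz", "holding_mv", "filter_khz"))]
  new("TraceRecord", tMS = dat$t_ms, iPA = dat$i_pA,
      holdingMV = holdingMV, samplingKHz = samplingKHz,
      filterKHz = filterKHz, meta = extra)
}

#' @rdname readTraceCSV
#' @param trace a [TraceRecord-class].
#' @return `writeTraceCSV()`: the path, invisibly.
#' @export
writeTraceCSV <- function(trace, path) {
  stopifnot(is(trace, "TraceRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_khz=%.10g", trace@samplingKHz), con)
  if (!is.na(trace@holdingMV))
    writeLines(sprintf("# holding_mv=%.10g", trace@holdingMV), con)
  if (!is.na(trace@filterKHz))
    writeLines(sprintf("# filter_khz=%.10g", trace@filterKHz), con)
  for (key in names(trace@meta)) {
    val <- trace@meta[[key]]
    if (is.null(val) || !length(val)) next
    writeLines(sprintf("# %s=%s", key, format(val[1], scientific = FALSE)),
               con)
  }
  writeLines("t_ms,i_pA", con)
  writeLines(sprintf("%.10g,%.10g", trace@tMS, trace@iPA), con)
  invisible(path)
}

#' Read a single-model PDB file as a coordinate frame
#'
#' Coordinate-only PDB reading (via bio3d): ATOM/HETATM records become a
#' [CoordinateFrame-class] with element-derived masses. Selections are
#' supplied as named lists of matching criteria on atom name, chain and
#' residue number, e.g. `list(name = "P")` or
#' `list(chain = "A", resid = 224:473)`.
#'
#' @param path PDB file path.
#' @param tmd,phosphorus,r2Chain optional selection lists populating the
#'   frame's `tmd`, `phosphorus` and `r2_chain` tags.
#' @return A [CoordinateFrame-class].
#' @export
readPDBFrame <- function(path, tmd = NULL, phosphorus = NULL,
                         r2Chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  if (!nrow(atoms)) stop("no coordinate records in '", path, "'")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  masses <- elementMass(atoms$elesy, atoms$elety)
  tags <- list()
  matchSel <- function(sel) {
    keep <- rep(TRUE, nrow(atoms))
    if (!is.null(sel$name))
      keep <- keep & trimws(atoms$elety) %in% sel$name
    if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
    if (!is.null(sel$resid)) keep <- keep & atoms$resno %in% sel$resid
    which(keep)
  }
  if (!is.null(tmd)) tags$tmd <- matchSel(tmd)
  if (!is.null(phosphorus)) tags$phosphorus <- matchSel(phosphorus)
  if (!is.null(r2Chain)) tags$r2_chain <- matchSel(r2Chain)
  coordinateFrame(xyz, masses, tags)
}

# Atomic masses (amu) by element symbol, with a fallback guess from the
# first letter of the atom name.
elementMass <- function(elesy, elety) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
              S = 32.06, MG = 24.305, CL = 35.45, K = 39.098,
              CA = 40.078, FE = 55.845, ZN = 65.38)
  masses["NA"] <- 22.99
  sym <- toupper(trimws(as.character(elesy)))
  missing <- is.na(sym) | !nzchar(sym)
  if (any(missing)) {
    fallback <- toupper(substr(gsub("[^A-Za-z].*", "",
                                    trimws(as.character(elety))), 1, 1))
    sym[missing] <- fallback[missing]
  }
  out <- masses[sym]
  out[is.na(out)] <- 12.011
  unname(out)
}
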