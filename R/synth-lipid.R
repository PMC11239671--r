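#' Generate synthetic lipid-binding geometry with known states
#'
#' Produces a piecewise-stationary 2-D Gaussian (dP, dR2-Cent) distance
#' series that dwells at each supplied state center in turn, together with
#' matching 3-D coordinate frames: a transmembrane-domain stand-in (rings
#' of atoms along the axis, so the smallest-moment principal axis of the
#' frame recovers the generating axis), a phosphorus marker atom at
#' perpendicular distance dP from the axis, and a short chain of atoms
#' whose center of mass sits at dR2-Cent.
#'
#' @param axis an [Axis-class]; the generating principal axis.
#' @param stateCenters k x 2 matrix (or list of length-2 vectors) of state
#'   centers (dP, dR2-Cent) in Angstrom; centers must be distinct.
#' @param dwellFrames frames spent at each center (recycled; >= 1).
#' @param jitterSD isotropic Gaussian jitter SD in Angstrom (>= 0).
#' @param seed optional integer seed.
#' @param makeFrames build the coordinate frames (set `FALSE` for
#'   large distance-only series).
#' @return A list with `series` (an [AxisDistanceSeries-class]) and
#'   `frames` (a list of [CoordinateFrame-class], or `NULL`).
#' @examples
#' ax <- new("Axis", direction = c(0, 0, 1), anchor = c(0, 0, 0))
#' g <- genLipidFrames(ax, rbind(c(5, 10), c(12, 20)), dwellFrames = 50,
#'                     jitterSD = 0.3, seed = 1)
#' @export
genLipidFrames <- function(axis, stateCenters, dwellFrames = 100,
                           jitterSD = 0, seed = NULL, makeFrames = TRUE) {
  stopifnot(is(axis, "Axis"), jitterSD >= 0)
  if (is.list(stateCenters)) stateCenters <- do.call(rbind, stateCenters)
  stateCenters <- as.matrix(stateCenters)
  stopifnot(ncol(stateCenters) == 2L)
  if (anyDuplicated(as.data.frame(stateCenters)))
    stop("state centers must be distinct")
  k <- nrow(stateCenters)
  dwellFrames <- rep_len(dwellFrames, k)
  stopifnot(all(dwellFrames >= 1))

  withSeed(seed, {
    stateIdx <- rep(seq_len(k), times = dwellFrames)
    n <- length(stateIdx)
    dP <- stateCenters[stateIdx, 1] + stats::rnorm(n, sd = jitterSD)
    dR2 <- stateCenters[stateIdx, 2] + stats::rnorm(n, sd = jitterSD)
    dP <- pmax(dP, 0)
    dR2 <- pmax(dR2, 0)
    series <- new("AxisDistanceSeries", dP = dP, dR2Cent = dR2,
                  meta = list(stateCenters = stateCenters,
                              dwellFrames = dwellFrames,
                              stateIndex = stateIdx,
                              jitterSD = jitterSD, seed = seed))
    frames <- if (makeFrames)
      lapply(seq_len(n), function(i)
        buildLipidFrame(axis, dP[i], dR2[i]))
    else NULL
    list(series = series, frames = frames)
  })
}

# Orthonormal basis perpendicular to a unit vector.
perpBasis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# One synthetic coordinate frame: TMD rings + phosphorus + R2 chain.
buildLipidFrame <- function(axis, dP, dR2, tmdHalfLengthA = 20,
                            tmdRadiusA = 8) {
  d <- axis@direction
  a <- axis@anchor
  b <- perpBasis(d)
  # TMD stand-in: rings of 8 atoms at 9 heights along the axis
  heights <- seq(-tmdHalfLengthA, tmdHalfLengthA, length.out = 9)
  angles <- seq(0, 2 * pi, length.out = 9L)[-9L]
  tmd <- do.call(rbind, lapply(heights, function(h)
    t(vapply(angles, function(th)
      a + h * d + tmdRadiusA * (cos(th) * b$e1 + sin(th) * b$e2),
      numeric(3)))))
  p <- a + dP * b$e1 + 5 * d  # phosphorus near the upper leaflet
  chainOffsets <- seq(-2, 2, length.out = 5)
  chain <- t(vapply(chainOffsets, function(h) a + dR2 * b$e1 + h * d,
                    numeric(3)))
  xyz <- rbind(tmd, p, chain)
  nT <- nrow(tmd)
  coordinateFrame(
    xyz,
    masses = c(rep(12, nT), 31, rep(12, 5)),
    tags = list(
      tmd = seq_len(nT),
      phosphorus = nT + 1L,
      r2_chain = nT + 1L + seq_len(5)))
}
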