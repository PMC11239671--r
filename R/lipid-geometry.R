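#' Smallest-moment principal axis of an atom selection
#'
#' Mass-weighted inertia tensor about the selection's center of mass; the
#' eigenvector of the smallest eigenvalue is the elongation (long) axis of
#' the selection, e.g. the transmembrane bundle axis. The sign is fixed by
#' a positive projection on the +z axis of the input frame.
#'
#' @param frame a [CoordinateFrame-class].
#' @param selection tag name of the atoms to use (default `"tmd"`), or an
#'   integer index vector.
#' @param degeneracyTol relative eigenvalue-gap tolerance below which the
#'   axis is declared ambiguous (near-spherical inertia).
#' @return An [Axis-class] anchored at the selection's center of mass.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' xyz <- cbind(cos(rep(th, 3)), sin(rep(th, 3)),
#'              rep(c(-5, 0, 5), each = 12))
#' fr <- coordinateFrame(xyz, tags = list(tmd = seq_len(nrow(xyz))))
#' principalAxisSmallestMoment(fr)
#' @export
principalAxisSmallestMoment <- function(frame, selection = "tmd",
                                        degeneracyTol = 1e-6) {
  stopifnot(is(frame, "CoordinateFrame"))
  idx <- if (is.character(selection)) {
    if (is.null(frame@tags[[selection]]))
      stop("no atoms tagged '", selection, "'")
    frame@tags[[selection]]
  } else as.integer(selection)
  if (length(idx) < 3L) stop("at least 3 atoms are required")
  xyz <- frame@xyz[idx, , drop = FALSE]
  m <- frame@masses[idx]
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  # inertia tensor I = sum m (|r|^2 I3 - r r^T)
  r2 <- rowSums(r^2)
  I3 <- diag(3) * sum(m * r2) - crossprod(r * sqrt(m))
  eig <- eigen(I3, symmetric = TRUE)
  vals <- eig$values  # descending
  if (abs(vals[2] - vals[3]) <= degeneracyTol * max(abs(vals), 1e-300))
    stop("degenerate inertia tensor: smallest-moment axis is ambiguous")
  v <- eig$vectors[, 3L]
  if (v[3] < 0 || (v[3] == 0 && v[1] < 0)) v <- -v
  new("Axis", direction = v / sqrt(sum(v^2)), anchor = com)
}

#' Perpendicular distances of the lipid markers from an axis
#'
#' Distance of the phosphorus atom (`dP`) and of the mass-weighted center
#' of the R2-fatty-acid-chain selection (`dR2Cent`) from the axis line.
#'
#' @param frame a [CoordinateFrame-class] with `phosphorus` and `r2_chain`
#'   tags.
#' @param axis an [Axis-class].
#' @return Named numeric vector `c(dP = , dR2Cent = )` in Angstrom.
#' @export
axisDistances <- function(frame, axis) {
  stopifnot(is(frame, "CoordinateFrame"), is(axis, "Axis"))
  pIdx <- frame@tags$phosphorus
  cIdx <- frame@tags$r2_chain
  if (!length(pIdx)) stop("empty 'phosphorus' selection")
  if (!length(cIdx)) stop("empty 'r2_chain' selection")
  p <- colMeans(frame@xyz[pIdx, , drop = FALSE])
  mc <- frame@masses[cIdx]
  cent <- colSums(frame@xyz[cIdx, , drop = FALSE] * mc) / sum(mc)
  c(dP = pointLineDistance(p, axis),
    dR2Cent = pointLineDistance(cent, axis))
}

pointLineDistance <- function(point, axis) {
  w <- point - axis@anchor
  proj <- sum(w * axis@direction)
  sqrt(max(0, sum(w^2) - proj^2))
}

#' Per-frame axis distances for a list of frames
#'
#' Computes the principal axis per frame (or uses a fixed axis) and
#' returns the (dP, dR2-Cent) series.
#'
#' @param frames list of [CoordinateFrame-class] objects.
#' @param axis an [Axis-class] to use for every frame, or `NULL` to
#'   recompute the smallest-moment axis of the `tmd` selection per frame.
#' @return An [AxisDistanceSeries-class].
#' @export
axisDistanceSeries <- function(frames, axis = NULL) {
  d <- vapply(frames, function(fr) {
    ax <- if (is.null(axis)) principalAxisSmallestMoment(fr) else axis
    axisDistances(fr, ax)
  }, numeric(2))
  new("AxisDistanceSeries", dP = d[1, ], dR2Cent = d[2, ], meta = list())
}

#' 2-D histogram of lipid-binding geometry with labeled states
#'
#' Bins the (dP, dR2-Cent) series into a 2-D histogram and identifies
#' highly populated states as thresholded local maxima with a minimum
#' separation, labeled S1 (most populated) downward. Mode populations are
#' frame counts under nearest-center assignment.
#'
#' @param series an [AxisDistanceSeries-class] with at least 100 frames.
#' @param binWidthA histogram bin width in Angstrom.
#' @param minCountFrac minimum bin count, as a fraction of the total frame
#'   count, for a bin to qualify as a mode.
#' @param minSeparationBins Chebyshev radius (in bins) within which a mode
#'   must dominate and within which weaker maxima are suppressed.
#' @return A [StateMap-class]; empty (with a warning) when no bin exceeds
#'   the threshold.
#' @examples
#' ax <- new("Axis", direction = c(0, 0, 1), anchor = c(0, 0, 0))
#' g <- genLipidFrames(ax, rbind(c(5, 10), c(12, 20)), dwellFrames = 200,
#'                     jitterSD = 0.3, seed = 1, makeFrames = FALSE)
#' stateHistogram(g$series)
#' @export
stateHistogram <- function(series, binWidthA = 0.5, minCountFrac = 0.01,
                           minSeparationBins = 2) {
  stopifnot(is(series, "AxisDistanceSeries"))
  n <- length(series@dP)
  if (n < 100) stop("at least 100 frames are required")

  mkBreaks <- function(x) {
    lo <- floor(min(x) / binWidthA) * binWidthA
    hi <- ceiling(max(x) / binWidthA) * binWidthA
    if (hi <= lo) hi <- lo + binWidthA
    seq(lo, hi, by = binWidthA)
  }
  bx <- mkBreaks(series@dP)
  by <- mkBreaks(series@dR2Cent)
  ix <- findInterval(series@dP, bx, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(series@dR2Cent, by, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0, length(bx) - 1L, length(by) - 1L)
  for (f in seq_len(n)) counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1

  thr <- minCountFrac * n
  sep <- as.integer(minSeparationBins)
  nr <- nrow(counts)
  nc <- ncol(counts)
  isMax <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cij <- counts[i, j]
      if (cij < thr) next
      nb <- counts[max(1, i - sep):min(nr, i + sep),
                   max(1, j - sep):min(nc, j + sep)]
      if (cij == max(nb)) isMax[i, j] <- TRUE
    }
  }
  cand <- which(isMax, arr.ind = TRUE)
  if (!nrow(cand)) {
    warning("no mode above the count threshold; empty state list")
    return(new("StateMap", breaksDP = bx, breaksDR2 = by, counts = counts,
               centers = matrix(numeric(), 0, 2,
                                dimnames = list(NULL, c("dP", "dR2Cent"))),
               populations = numeric(), labels = character()))
  }
  # suppress ties within the separation radius, keeping the larger count
  ord <- order(counts[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    if (q == 1L) {
      kept[q] <- TRUE
      next
    }
    prior <- cand[kept, , drop = FALSE]
    dChe <- pmax(abs(prior[, 1] - cand[q, 1]), abs(prior[, 2] - cand[q, 2]))
    kept[q] <- all(dChe > sep)
  }
  cand <- cand[kept, , drop = FALSE]

  midX <- (bx[-1] + bx[-length(bx)]) / 2
  midY <- (by[-1] + by[-length(by)]) / 2
  centers <- cbind(dP = midX[cand[, 1]], dR2Cent = midY[cand[, 2]])

  # populations under nearest-center assignment of all frames
  d2 <- outer(series@dP, centers[, 1], "-")^2 +
    outer(series@dR2Cent, centers[, 2], "-")^2
  assign <- max.col(-d2, ties.method = "first")
  pops <- tabulate(assign, nbins = nrow(centers))
  o <- order(pops, decreasing = TRUE)
  centers <- centers[o, , drop = FALSE]
  pops <- pops[o]
  new("StateMap", breaksDP = bx, breaksDR2 = by, counts = counts,
      centers = centers, populations = as.numeric(pops),
      labels = paste0("S", seq_len(nrow(centers))))
}

#' Classify frames against a state map
#'
#' Nearest-mode assignment with an optional cutoff radius beyond which
#' frames are labeled `"unassigned"`. Returns the per-frame labels, the
#' visit order (runs of identical labels), per-state dwell totals and the
#' first-passage path to the most populated state S1 when reached.
#'
#' @param series an [AxisDistanceSeries-class].
#' @param statemap a non-empty [StateMap-class].
#' @param cutoffA assignment cutoff radius in Angstrom (default `Inf`).
#' @return A list with `labels`, `visitOrder`, `dwellFrames` (named totals
#'   summing to the frame count) and `pathToS1` (character, `NULL` when S1
#'   is never reached).
#' @export
classifyFrames <- function(series, statemap, cutoffA = Inf) {
  stopifnot(is(series, "AxisDistanceSeries"), is(statemap, "StateMap"))
  if (!length(statemap@labels)) stop("empty state map")
  d2 <- outer(series@dP, statemap@centers[, 1], "-")^2 +
    outer(series@dR2Cent, statemap@centers[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)])
  labels <- ifelse(dmin < cutoffA, statemap@labels[nearest], "unassigned")
  r <- rle(labels)
  dwell <- tapply(rep(1L, length(labels)), labels, sum)
  dwell <- stats::setNames(as.numeric(dwell), names(dwell))
  firstS1 <- match("S1", labels)
  pathToS1 <- if (!is.na(firstS1)) {
    upto <- rle(labels[seq_len(firstS1)])$values
    upto[upto != "unassigned"]
  } else NULL
  list(labels = labels, visitOrder = r$values, dwellFrames = dwell,
       pathToS1 = pathToS1)
}
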