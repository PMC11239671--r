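#' Idealize a single-channel trace by half-amplitude threshold crossing
#'
#' Samples are classified open/closed by crossing
#' `thresholdFrac * unitaryAmpPA` (sign-aware: the unitary amplitude may be
#' negative at negative potentials). A hysteresis band of
#' `hysteresisFrac * |unitaryAmpPA|` around the threshold suppresses
#' chatter from recording noise. Runs shorter than `deadTimeMS` are merged
#' into their neighbors.
#'
#' @param trace a [TraceRecord-class].
#' @param unitaryAmpPA unitary current amplitude in pA (nonzero). If its
#'   sign is inconsistent with the holding-voltage convention a warning is
#'   emitted and the magnitude is used.
#' @param thresholdFrac threshold as a fraction of the unitary amplitude
#'   (default 0.5, the field-standard half-amplitude criterion).
#' @param deadTimeMS minimum resolvable event duration in ms.
#' @param hysteresisFrac width of the hysteresis band as a fraction of the
#'   unitary amplitude.
#' @return An [EventSequence-class] with states `closed`/`open`.
#' @examples
#' m <- twoStateGatingModel(26, 41)
#' ev <- simulateGating(m, 90, 2000, seed = 1)
#' tr <- renderTrace(ev, m, 90, noiseSdPA = 0.1, samplingKHz = 10, seed = 2)
#' idealize(tr, unitaryAmpPA = 5.4)
#' @export
idealize <- function(trace, unitaryAmpPA, thresholdFrac = 0.5,
                     deadTimeMS = 0, hysteresisFrac = 0.1) {
  stopifnot(is(trace, "TraceRecord"))
  if (unitaryAmpPA == 0) stop("unitaryAmpPA must be nonzero")
  if (!is.na(trace@holdingMV) && trace@holdingMV != 0 &&
      sign(unitaryAmpPA) != 0 &&
      sign(unitaryAmpPA) != sign(trace@holdingMV)) {
    warning("unitaryAmpPA sign inconsistent with holding potential; ",
            "proceeding on magnitude")
  }
  # work on the signed projection onto the open level
  x <- trace@iPA * sign(unitaryAmpPA)
  amp <- abs(unitaryAmpPA)
  upper <- (thresholdFrac + hysteresisFrac / 2) * amp
  lower <- (thresholdFrac - hysteresisFrac / 2) * amp

  # hysteresis classification: samples above the upper threshold are open,
  # below the lower are closed, in-band samples keep the previous state
  n <- length(x)
  v <- rep(NA_integer_, n)
  v[x > upper] <- 1L
  v[x < lower] <- 0L
  known <- !is.na(v)
  locf <- cummax(seq_len(n) * known)
  open <- logical(n)
  open[locf > 0L] <- v[locf[locf > 0L]] == 1L  # start closed until known

  r <- rle(open)
  durations <- r$lengths / trace@samplingKHz
  states <- ifelse(r$values, "open", "closed")
  if (deadTimeMS > 0 && length(durations) > 1L) {
    merged <- mergeShortEvents(states, durations, deadTimeMS)
    states <- merged$states
    durations <- merged$durations
  }
  eventSequence(states, durations)
}

# Absorb runs shorter than deadTimeMS into their neighbors, shortest first.
mergeShortEvents <- function(states, durations, deadTimeMS) {
  repeat {
    if (length(durations) <= 1L) break
    short <- which(durations < deadTimeMS)
    if (!length(short)) break
    j <- short[which.min(durations[short])]
    # merging flips the short run's state to its neighbors'
    keep <- setdiff(seq_along(durations), j)
    nbr <- if (j == 1L) 2L else j - 1L
    durations[nbr] <- durations[nbr] + durations[j]
    states <- states[keep]
    durations <- durations[keep]
    # re-collapse adjacent equal states
    if (length(states) > 1L) {
      grp <- cumsum(c(TRUE, states[-1L] != states[-length(states)]))
      durations <- as.numeric(tapply(durations, grp, sum))
      states <- states[!duplicated(grp)]
    }
  }
  list(states = states, durations = durations)
}

#' Open probability of an idealized record
#'
#' Fraction of total time spent in conducting states. Subconductance
#' occupancy counts as open by default (set `countSubAsOpen = FALSE` to
#' restrict to the full open level).
#'
#' @param events an [EventSequence-class] (nonempty).
#' @param countSubAsOpen logical; include `sub*` states as open.
#' @return Open probability in `[0, 1]`.
#' @examples
#' ev <- eventSequence(c("closed", "open", "closed"), c(10, 10, 10))
#' openProbability(ev)
#' @export
openProbability <- function(events, countSubAsOpen = TRUE) {
  stopifnot(is(events, "EventSequence"), length(events@states) > 0)
  base <- sub("[0-9]*$", "", events@states)
  isOpen <- base == "open" | (countSubAsOpen & base == "sub")
  sum(events@durationsMS[isOpen]) / events@totalMS
}

#' Per-level occupancy of an idealized record
#'
#' @param events an [EventSequence-class].
#' @return Named numeric vector of time fractions per state label.
#' @export
stateOccupancy <- function(events) {
  stopifnot(is(events, "EventSequence"), length(events@states) > 0)
  tab <- tapply(events@durationsMS, events@states, sum)
  stats::setNames(as.numeric(tab) / events@totalMS, names(tab))
}

#' Maximum-likelihood single-exponential dwell-time fit
#'
#' For exponentially distributed dwells left-truncated at the dead time,
#' memorylessness gives the closed-form MLE `tau = mean(durations) -
#' deadTimeMS`.
#'
#' @param durationsMS dwell durations in ms (at least 2, all greater than
#'   the dead time).
#' @param deadTimeMS left-truncation dead time in ms.
#' @return A [DwellFit-class].
#' @examples
#' fitDwellExponential(c(2, 4, 6))  # tau = 4
#' @export
fitDwellExponential <- function(durationsMS, deadTimeMS = 0) {
  if (length(durationsMS) < 2L)
    stop("at least 2 dwell durations are required")
  if (any(durationsMS <= deadTimeMS))
    stop("all durations must exceed the dead time")
  tau <- mean(durationsMS) - deadTimeMS
  ll <- sum(stats::dexp(durationsMS - deadTimeMS, rate = 1 / tau,
                        log = TRUE))
  new("DwellFit", tauMS = tau, nEvents = length(durationsMS),
      logLik = ll, deadTimeMS = deadTimeMS)
}

#' Dwell durations of one state from an idealized record
#'
#' Truncated first and last events are dropped (their dwells are censored
#' by the recording window).
#'
#' @param events an [EventSequence-class].
#' @param state state label to extract (`"open"` or `"closed"`; matched on
#'   the base label so `sub` counts with `open` when
#'   `countSubAsOpen = TRUE`).
#' @param countSubAsOpen logical, as in [openProbability()].
#' @return Numeric vector of dwell durations in ms.
#' @export
dwellDurations <- function(events, state = c("open", "closed"),
                           countSubAsOpen = TRUE) {
  state <- match.arg(state)
  stopifnot(is(events, "EventSequence"))
  n <- length(events@states)
  if (n <= 2L) return(numeric())
  idx <- 2:(n - 1L)
  base <- sub("[0-9]*$", "", events@states[idx])
  if (countSubAsOpen) base[base == "sub"] <- "open"
  events@durationsMS[idx][base == state]
}

#' Gaussian-mixture fit of a current-amplitude histogram
#'
#' Fits the sample amplitude distribution with a sum of `nComponents`
#' Gaussians by expectation-maximization, initialized from k-means with
#' `restarts` additional random restarts (seeded, reproducible). Components
#' are reported sorted by mean; peak separation over pooled SD is returned
#' as a quality metric.
#'
#' @param trace a [TraceRecord-class] (or numeric amplitude vector).
#' @param nComponents number of Gaussian components (default 2: closed and
#'   open levels).
#' @param restarts number of random EM restarts beyond the k-means start.
#' @param maxIter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @param seed integer seed for the restarts.
#' @return An [AmpHistFit-class].
#' @examples
#' x <- c(rnorm(700, 0, 0.2), rnorm(300, -3, 0.2))
#' fit <- amplitudeHistogramFit(x, nComponents = 2, seed = 1)
#' @export
amplitudeHistogramFit <- function(trace, nComponents = 2, restarts = 5,
                                  maxIter = 500, tol = 1e-8, seed = 1) {
  x <- if (is(trace, "TraceRecord")) trace@iPA else as.numeric(trace)
  if (length(x) < 10 * nComponents)
    stop("trace too short for a ", nComponents, "-component fit")

  uniq <- unique(x)
  if (length(uniq) < nComponents) {
    # degenerate noiseless single-level data: one dominant component
    means <- c(uniq, rep(uniq[1], nComponents - length(uniq)))
    sds <- rep(max(1e-8, stats::sd(x), na.rm = TRUE), nComponents)
    sds[!is.finite(sds) | sds == 0] <- 1e-8
    w <- c(rep(1 - 1e-6, 1), rep(1e-6 / (nComponents - 1), nComponents - 1))
    o <- order(means)
    return(new("AmpHistFit", means = means[o], sds = sds[o],
               weights = w[o] / sum(w),
               breaks = range(x) + c(-1e-8, 1e-8), counts = length(x),
               separation = 0, logLik = NA_real_))
  }

  best <- NULL
  withSeed(seed, {
    starts <- vector("list", restarts + 1L)
    km <- suppressWarnings(
      stats::kmeans(x, centers = nComponents, nstart = 3))
    starts[[1L]] <- sort(as.numeric(km$centers))
    for (r in seq_len(restarts))
      starts[[r + 1L]] <- sort(sample(x, nComponents))
    for (st in starts) {
      fit <- try(emGaussian1D(x, st, maxIter, tol), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
  })
  if (is.null(best))
    stop("EM failed to converge after ", restarts + 1L,
         " starts; check the amplitude distribution")

  o <- order(best$means)
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  sep <- if (nComponents >= 2) {
    dm <- diff(range(best$means))
    pooled <- sqrt(sum(best$weights * best$sds^2))
    dm / pooled
  } else 0
  new("AmpHistFit", means = best$means[o], sds = best$sds[o],
      weights = best$weights[o] / sum(best$weights),
      breaks = h$breaks, counts = as.numeric(h$counts),
      separation = sep, logLik = best$logLik)
}

# Plain 1-D Gaussian-mixture EM with an SD floor against collapse.
emGaussian1D <- function(x, means, maxIter, tol) {
  k <- length(means)
  n <- length(x)
  sds <- rep(stats::sd(x) / k, k)
  sdFloor <- max(1e-10, 1e-6 * stats::sd(x))
  w <- rep(1 / k, k)
  ll <- -Inf
  for (iter in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, means[j], sds[j]), numeric(n))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    llNew <- sum(log(rowsum_))
    resp <- dens / rowsum_
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    means <- colSums(resp * x) / nk
    sds <- sqrt(pmax(
      colSums(resp * (outer(x, means, "-")^2)) / nk, sdFloor^2))
    if (is.finite(ll) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
      ll <- llNew
      break
    }
    ll <- llNew
  }
  list(means = means, sds = sds, weights = w, logLik = ll)
}

#' Polynomial fit of the unitary current-voltage relationship
#'
#' Least-squares polynomial fit of unitary amplitudes against voltage, the
#' standard treatment of single-channel I-V data that rectifies weakly.
#'
#' @param voltageMV voltages in mV.
#' @param amplitudePA unitary amplitudes in pA.
#' @param degree polynomial degree (default 3; needs at least
#'   `degree + 1` points).
#' @return A list of class `"unitaryIV"` with `coefficients` (ascending
#'   powers), `degree`, `residuals`, `fitted`, `voltageMV`,
#'   `amplitudePA` and `predict(v)`.
#' @examples
#' v <- seq(-150, 90, by = 30)
#' fit <- unitaryIVFit(v, 0.06 * v, degree = 1)
#' @export
unitaryIVFit <- function(voltageMV, amplitudePA, degree = 3) {
  n <- length(voltageMV)
  stopifnot(length(amplitudePA) == n)
  if (n < degree + 1)
    stop("underdetermined: ", n, " points for degree ", degree)
  fit <- stats::lm(amplitudePA ~ stats::poly(voltageMV, degree, raw = TRUE))
  beta <- unname(stats::coef(fit))
  predictFun <- function(v)
    drop(outer(v, 0:degree, `^`) %*% beta)
  structure(list(
    coefficients = beta, degree = degree,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    voltageMV = voltageMV, amplitudePA = amplitudePA,
    predict = predictFun
  ), class = "unitaryIV")
}

#' Reconstruct the macroscopic I-V curve from unitary current and Po
#'
#' The elementwise product `i(V) * Po(V)` reconstructs the expected
#' macroscopic current per channel; a strongly asymmetric Po imposed on a
#' weakly rectifying unitary current yields the strongly rectifying
#' whole-cell profile.
#'
#' @param uiv a `"unitaryIV"` fit from [unitaryIVFit()].
#' @param poCurve data frame with columns `voltage_mV` and `po`.
#' @return A data frame `voltage_mV`, `i_pA` (interpolated unitary
#'   current), `po`, `i_po` plus attribute `"rectification"`, the
#'   rectification index of the product curve when both +100 and -150 mV
#'   are inside the voltage range.
#' @export
reconstructMacroscopic <- function(uiv, poCurve) {
  stopifnot(inherits(uiv, "unitaryIV"),
            all(c("voltage_mV", "po") %in% names(poCurve)))
  v <- poCurve$voltage_mV
  rngFit <- range(uiv$voltageMV)
  if (max(v) < rngFit[1] || min(v) > rngFit[2])
    stop("voltage ranges of the unitary fit and the Po curve are disjoint")
  i <- uiv$predict(v)
  out <- data.frame(voltage_mV = v, i_pA = i, po = poCurve$po,
                    i_po = i * poCurve$po)
  rect <- if (min(v) <= -150 && max(v) >= 100) {
    iv <- data.frame(voltage_mV = out$voltage_mV, i_pA = out$i_po)
    tryCatch(rectificationIndex(iv), error = function(e) NA_real_)
  } else NA_real_
  attr(out, "rectification") <- rect
  out
}

#' Rectification index of an I-V curve
#'
#' The absolute ratio of the current at a negative test potential over the
#' current at a positive one, `|I(-150)| / |I(+100)|` by default; values
#' above 1 indicate inward rectification.
#'
#' @param iv data frame with columns `voltage_mV` and `i_pA` (currents may
#'   also be densities).
#' @param vNegMV,vPosMV test potentials in mV (must be inside the curve's
#'   voltage range; currents are linearly interpolated).
#' @return The rectification index (positive scalar).
#' @examples
#' iv <- data.frame(voltage_mV = seq(-150, 100, 10),
#'                  i_pA = seq(-150, 100, 10))
#' rectificationIndex(iv)  # 1.5 for an Ohmic curve through 0
#' @export
rectificationIndex <- function(iv, vNegMV = -150, vPosMV = 100) {
  stopifnot(all(c("voltage_mV", "i_pA") %in% names(iv)))
  rng <- range(iv$voltage_mV)
  if (vNegMV < rng[1] || vPosMV > rng[2])
    stop("test potentials outside the curve's voltage range")
  iNeg <- stats::approx(iv$voltage_mV, iv$i_pA, xout = vNegMV)$y
  iPos <- stats::approx(iv$voltage_mV, iv$i_pA, xout = vPosMV)$y
  if (iPos == 0)
    stop("current at the positive test potential is zero; ratio undefined")
  abs(iNeg) / abs(iPos)
}
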