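#' Simulate single-channel gating as an exact continuous-time Markov chain
#'
#' Event-driven (Gillespie) realization of the gating model at a fixed
#' holding potential: exponential holding times drawn from each state's
#' total exit rate, categorical jumps proportional to the outgoing rates.
#' Dwell-time distributions are therefore exactly exponential, which the
#' downstream dwell-time recovery tests rely on. If the initial state has
#' no exit path (e.g. the opening rate is zero at 0 mV) a single event
#' spanning the full duration is returned.
#'
#' @param model a [GatingModel-class].
#' @param voltageMV holding potential in mV.
#' @param durationMS simulated duration in ms (> 0).
#' @param seed optional integer seed for reproducibility.
#' @param initialState index of the starting state (default 1, by
#'   convention the closed state).
#' @return An [EventSequence-class]; the final event is truncated at
#'   `durationMS`.
#' @examples
#' m <- twoStateGatingModel(tauOpenMS = 26, tauClosedMS = 41)
#' ev <- simulateGating(m, voltageMV = 90, durationMS = 5000, seed = 1)
#' openProbability(ev)
#' @export
simulateGating <- function(model, voltageMV, durationMS, seed = NULL,
                           initialState = 1L) {
  stopifnot(is(model, "GatingModel"), durationMS > 0)
  n <- length(model@stateLabels)
  Q <- model@rates(voltageMV)
  checkRateMatrix(Q, n)
  exitRates <- -diag(Q)
  jumpProb <- Q
  diag(jumpProb) <- 0
  for (i in seq_len(n))
    if (exitRates[i] > 0) jumpProb[i, ] <- jumpProb[i, ] / exitRates[i]

  withSeed(seed, {
    cap <- 1024L
    states <- integer(cap)
    durations <- numeric(cap)
    k <- 0L
    t <- 0
    s <- initialState
    while (t < durationMS) {
      rate <- exitRates[s]
      dwell <- if (rate > 0) stats::rexp(1L, rate) else Inf
      dwell <- min(dwell, durationMS - t)
      k <- k + 1L
      if (k > cap) {
        cap <- cap * 2L
        length(states) <- cap
        length(durations) <- cap
      }
      states[k] <- s
      durations[k] <- dwell
      t <- t + dwell
      if (t >= durationMS) break
      s <- sample.int(n, 1L, prob = jumpProb[s, ])
    }
    eventSequence(model@stateLabels[states[seq_len(k)]],
                  durations[seq_len(k)])
  })
}

#' Render an idealized event sequence as a sampled current trace
#'
#' Per-sample current is `conductance(state) * (V - Erev) * 1e-3` pA (pS x
#' mV gives fA, hence the 1e-3), plus independent Gaussian recording noise.
#' An optional moving-average low-pass filter emulating the recording
#' chain's 2 kHz filtering is applied after the noise.
#'
#' @param events an [EventSequence-class].
#' @param model the generating [GatingModel-class] (for conductances and
#'   Erev).
#' @param voltageMV holding potential in mV.
#' @param noiseSdPA Gaussian noise SD in pA (>= 0).
#' @param samplingKHz sampling rate in kHz.
#' @param filterKHz optional low-pass cutoff in kHz; requires
#'   `samplingKHz >= 2 * filterKHz`.
#' @param seed optional integer seed.
#' @return A [TraceRecord-class].
#' @examples
#' m <- twoStateGatingModel(tauOpenMS = 26, tauClosedMS = 41)
#' ev <- simulateGating(m, 90, 1000, seed = 1)
#' tr <- renderTrace(ev, m, 90, noiseSdPA = 0.1, samplingKHz = 10, seed = 2)
#' @export
renderTrace <- function(events, model, voltageMV, noiseSdPA = 0,
                        samplingKHz = 10, filterKHz = NA_real_,
                        seed = NULL) {
  stopifnot(is(events, "EventSequence"), is(model, "GatingModel"))
  if (noiseSdPA < 0) stop("noiseSdPA must be non-negative")
  if (!is.na(filterKHz) && samplingKHz < 2 * filterKHz)
    stop("sampling rate must be at least twice the filter cutoff")

  levelOf <- stats::setNames(
    model@conductancePS * (voltageMV - model@erevMV) * 1e-3,
    model@stateLabels)
  nSamples <- floor(events@totalMS * samplingKHz)
  tMS <- (seq_len(nSamples) - 0.5) / samplingKHz  # sample-midpoint times
  bounds <- cumsum(events@durationsMS)
  idx <- findInterval(tMS, c(0, bounds), left.open = TRUE,
                      rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(events@states)] <- length(events@states)
  i <- unname(levelOf[events@states[idx]])

  withSeed(seed, {
    if (noiseSdPA > 0)
      i <- i + stats::rnorm(nSamples, sd = noiseSdPA)
    if (!is.na(filterKHz)) {
      w <- max(1L, round(samplingKHz / filterKHz / 2) * 2L + 1L)
      i <- stats::filter(i, rep(1 / w, w), sides = 2)
      pad <- (w - 1L) / 2L
      i[seq_len(pad)] <- i[pad + 1L]
      i[nSamples - seq_len(pad) + 1L] <- i[nSamples - pad]
      i <- as.numeric(i)
    }
    traceRecord(i, samplingKHz, holdingMV = voltageMV,
                filterKHz = filterKHz,
                meta = list(seed = seed, noiseSdPA = noiseSdPA),
                tMS = tMS)
  })
}
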