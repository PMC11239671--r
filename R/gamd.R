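#' Harmonic boost potential
#'
#' The Gaussian-accelerated boost raises the potential only below the
#' reference energy: `dV = 0.5 * k * (E - V)^2` when `V < E`, else 0. The
#' modified potential is `V* = V + dV`, which is monotone non-decreasing
#' in V whenever the parameters satisfy the `Vmax <= E <= Vmin + 1/k`
#' criterion.
#'
#' @param V potential energy value(s), in the unit of `params`.
#' @param params a [BoostParams-class].
#' @return The boost `dV` (same length as `V`), always >= 0.
#' @examples
#' p <- new("BoostParams", E = 1, k = 2, sigma0 = 6)
#' boostPotential(0, p)  # 0.5 * 2 * 1^2 = 1
#' boostPotential(2, p)  # 0 above the reference energy
#' @export
boostPotential <- function(V, params) {
  stopifnot(is(params, "BoostParams"))
  ifelse(V < params@E, 0.5 * params@k * (params@E - V)^2, 0)
}

#' @rdname boostPotential
#' @return `modifiedPotential()`: `V + boostPotential(V, params)`.
#' @export
modifiedPotential <- function(V, params) V + boostPotential(V, params)

#' Select boost parameters from potential statistics
#'
#' The canonical Gaussian-accelerated-dynamics parameterization: the
#' effective force constant `k0` (dimensionless, in (0, 1]) is chosen so
#' the boost standard deviation stays below `sigma0`, then
#' `k = k0 / (Vmax - Vmin)`. With the lower bound the reference energy is
#' `E = Vmax`; with the upper (more aggressive) bound `E = Vmin + 1/k`,
#' with `k0` adjusted so the bound criterion `Vmax <= E <= Vmin + 1/k`
#' still holds. Returned parameters always satisfy that criterion.
#'
#' @param Vmax,Vmin,Vavg maximum, minimum and average potential energies
#'   collected from a preparatory run (same unit as `sigma0`).
#' @param sigmaV standard deviation of the potential (> 0).
#' @param sigma0 upper limit of the boost standard deviation (default the
#'   production value 6.0 kcal/mol).
#' @param bound `"upper"` (default, more aggressive) or `"lower"`.
#' @param unit energy unit tag.
#' @return A [BoostParams-class].
#' @examples
#' selectBoostParams(Vmax = -10, Vmin = -30, Vavg = -18, sigmaV = 2)
#' @export
selectBoostParams <- function(Vmax, Vmin, Vavg, sigmaV, sigma0 = 6,
                              bound = c("upper", "lower"),
                              unit = "kcal/mol") {
  bound <- match.arg(bound)
  stopifnot(Vmax > Vmin, sigmaV > 0, sigma0 > 0)
  if (Vavg >= Vmax) stop("Vavg must be below Vmax")
  k0 <- min(1, (sigma0 / sigmaV) * (Vmax - Vmin) / (Vmax - Vavg))
  if (bound == "upper") {
    # E = Vmin + 1/k requires k0 <= (1 - sigma0/sigmaV) *
    # (Vmax - Vmin)/(Vavg - Vmin); fall back to the lower bound otherwise
    k0u <- (1 - sigma0 / sigmaV) * (Vmax - Vmin) / (Vavg - Vmin)
    if (k0u > 0 && k0u <= 1) {
      k <- k0u / (Vmax - Vmin)
      E <- Vmin + 1 / k
    } else {
      # upper bound infeasible; fall back to the lower-bound choice
      k <- k0 / (Vmax - Vmin)
      E <- Vmax
    }
  } else {
    k <- k0 / (Vmax - Vmin)
    E <- Vmax
  }
  params <- new("BoostParams", E = E, k = k, sigma0 = sigma0,
                bound = bound, unit = unit)
  if (!(Vmax <= E + 1e-9 && E <= Vmin + 1 / k + 1e-9))
    stop("internal error: selected parameters violate the bound criterion")
  params
}

#' One-dimensional potentials for the Langevin demonstrator
#'
#' `doubleWellPotential()` returns the quartic double well
#' `V(x) = barrier * (x^2 - 1)^2` with minima at x = -1, +1 and a barrier
#' of height `barrier` at x = 0, the smallest system exhibiting
#' barrier-crossing kinetics.
#'
#' @param barrier barrier height (energy units of the simulation).
#' @return A list with functions `V(x)` and `dV(x)` and the field
#'   `barrier`.
#' @export
doubleWellPotential <- function(barrier = 4) {
  list(
    V = function(x) barrier * (x^2 - 1)^2,
    dV = function(x) 4 * barrier * x * (x^2 - 1),
    barrier = barrier)
}

#' Overdamped Langevin dynamics on a (optionally boosted) 1-D potential
#'
#' Desk-scale demonstrator of Gaussian-accelerated sampling: overdamped
#' Langevin (Brownian) dynamics integrated by Euler-Maruyama on the
#' modified potential `V* = V + dV`. Omitting `params` runs on the bare
#' potential; this is exactly equivalent to any boost whose reference
#' energy lies at or below the minimum sampled potential.
#'
#' @param potential a potential list as from [doubleWellPotential()].
#' @param params a [BoostParams-class] or `NULL` for unboosted dynamics.
#' @param steps number of integration steps.
#' @param dt time step (reduced units).
#' @param kT thermal energy (same unit as the potential).
#' @param friction friction coefficient gamma.
#' @param x0 initial position.
#' @param seed optional integer seed.
#' @return A list with `x` (positions, length `steps + 1`), `dV`
#'   (per-step boost, length `steps + 1`), `crossings` (sign-change count
#'   of x, a barrier-crossing proxy for the double well).
#' @examples
#' pot <- doubleWellPotential(4)
#' traj <- runToyGaMD(pot, NULL, steps = 2000, seed = 1)
#' @export
runToyGaMD <- function(potential, params = NULL, steps = 10000, dt = 0.005,
                       kT = 1, friction = 1, x0 = -1, seed = NULL) {
  stopifnot(steps >= 1, dt > 0, kT > 0, friction > 0)
  force <- if (is.null(params)) {
    function(x) -potential$dV(x)
  } else {
    stopifnot(is(params, "BoostParams"))
    function(x) {
      v <- potential$V(x)
      f <- -potential$dV(x)
      if (v < params@E) f * (1 - params@k * (params@E - v)) else f
    }
  }
  boostAt <- if (is.null(params)) function(x) 0 else
    function(x) boostPotential(potential$V(x), params)

  withSeed(seed, {
    x <- numeric(steps + 1L)
    dV <- numeric(steps + 1L)
    x[1L] <- x0
    dV[1L] <- boostAt(x0)
    noiseSd <- sqrt(2 * kT * dt / friction)
    xi <- stats::rnorm(steps, sd = noiseSd)
    xc <- x0
    for (i in seq_len(steps)) {
      xc <- xc + dt * force(xc) / friction + xi[i]
      if (!is.finite(xc) || abs(xc) > 1e6)
        stop("trajectory diverged at step ", i,
             "; reduce dt or the force constant")
      x[i + 1L] <- xc
      dV[i + 1L] <- boostAt(xc)
    }
    s <- sign(x)
    s <- s[s != 0]
    crossings <- sum(s[-1] != s[-length(s)])
    list(x = x, dV = dV, crossings = crossings)
  })
}
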