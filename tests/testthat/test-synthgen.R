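test_that("gating simulation reproduces the two-state stationary open fraction", {
  # analytic oracle: pi_open = tauOpen / (tauOpen + tauClosed)
  m <- twoStateGatingModel(tauOpenMS = 26, tauClosedMS = 41)
  ev <- simulateGating(m, voltageMV = 90, durationMS = 4e5, seed = 101)
  expect_gt(length(ev@states), 1e4)
  po <- openProbability(ev)
  nCycles <- length(ev@states) / 2
  se <- sqrt(26 / 67 * (1 - 26 / 67) / nCycles) * 2  # conservative
  expect_lt(abs(po - 26 / 67), 3 * se + 0.01)
})

test_that("mean dwell in each state equals the inverse total exit rate", {
  m <- twoStateGatingModel(tauOpenMS = 15, tauClosedMS = 40)
  ev <- simulateGating(m, 90, 3e5, seed = 11)
  open <- dwellDurations(ev, "open")
  closed <- dwellDurations(ev, "closed")
  expect_lt(abs(mean(open) - 15), 3 * 15 / sqrt(length(open)))
  expect_lt(abs(mean(closed) - 40), 3 * 40 / sqrt(length(closed)))
})

test_that("a state with no exit path yields a single full-duration event", {
  m <- defaultGatingModel()
  ev <- simulateGating(m, voltageMV = 0, durationMS = 5000, seed = 1)
  expect_identical(ev@states, "closed")
  expect_equal(ev@durationsMS, 5000)
})

test_that("gating simulation is reproducible for a fixed seed", {
  m <- defaultGatingModel()
  a <- simulateGating(m, 90, 20000, seed = 42)
  b <- simulateGating(m, 90, 20000, seed = 42)
  expect_identical(a@states, b@states)
  expect_identical(a@durationsMS, b@durationsMS)
})

test_that("invalid rate matrices are rejected", {
  Qneg <- matrix(c(-1, 1, -0.5, 0.5), 2, byrow = TRUE)  # negative off-diag
  expect_error(gatingModel(c("closed", "open"), c(0, 60), Qneg),
               "non-negative")
  Qrow <- matrix(c(-1, 2, 1, -1), 2, byrow = TRUE)  # bad row sums
  expect_error(gatingModel(c("closed", "open"), c(0, 60), Qrow),
               "row")
  expect_error(gatingModel(c("closed", "open"), c(5, 60),
                           matrix(c(-1, 1, 1, -1), 2)),
               "closed-state conductance")
})

test_that("rendered open level follows Ohm's law and noise has the requested SD", {
  m <- twoStateGatingModel(tauOpenMS = 26, tauClosedMS = 41,
                           conductancePS = 60, erevMV = 0)
  ev <- eventSequence(c("closed", "open"), c(500, 2000))
  tr0 <- renderTrace(ev, m, 90, noiseSdPA = 0, samplingKHz = 10)
  openSamples <- tr0@iPA[tr0@tMS > 500]
  expect_true(all(openSamples == 60 * 90 * 1e-3))  # 5.4 pA
  expect_true(all(tr0@iPA[tr0@tMS < 500] == 0))

  trN <- renderTrace(ev, m, 90, noiseSdPA = 0.1, samplingKHz = 10,
                     seed = 3)
  sdHat <- sd(trN@iPA[trN@tMS < 500])  # >= 4999 baseline samples
  expect_lt(abs(sdHat - 0.1) / 0.1, 0.05)
})

test_that("noise-free render followed by idealization recovers the events", {
  m <- twoStateGatingModel(tauOpenMS = 26, tauClosedMS = 41)
  # every dwell spans >= 2 samples at 10 kHz (>= 0.2 ms)
  set.seed(7)
  durations <- round(rexp(200, 1 / 30) + 0.3, 1)
  ev <- eventSequence(rep(c("closed", "open"), 100), durations)
  tr <- renderTrace(ev, m, 90, noiseSdPA = 0, samplingKHz = 10)
  id <- idealize(tr, unitaryAmpPA = 5.4)
  expect_identical(id@states, ev@states)
  expect_equal(id@durationsMS, ev@durationsMS, tolerance = 0.2)
  expect_lt(abs(openProbability(id) - openProbability(ev)), 0.01)
})

test_that("renderTrace validates its inputs", {
  m <- twoStateGatingModel(10, 10)
  ev <- eventSequence(c("closed", "open"), c(10, 10))
  expect_error(renderTrace(ev, m, 90, noiseSdPA = -1), "non-negative")
  expect_error(renderTrace(ev, m, 90, samplingKHz = 2, filterKHz = 2),
               "twice")
})

test_that("dose-response generator follows the Hill equation exactly", {
  # midpoint
  dr <- genDoseResponse(0.5, -1.301, 0.5)
  expect_equal(dr@responsePct, 50)
  # direct evaluation at X = 1, ic50 = 0.1, h = -1.301
  dr2 <- genDoseResponse(0.10, -1.301, 1.0)
  expect_equal(dr2@responsePct, 100 / (1 + 10^1.301), tolerance = 1e-12)
  # limits with a negative slope
  lims <- genDoseResponse(0.10, -1.301, c(1e-8, 1e8))
  expect_gt(lims@responsePct[1], 99.99)
  expect_lt(lims@responsePct[2], 0.01)
  expect_error(genDoseResponse(0.1, 0, 1), "degenerate")
  # replicate structure and reproducibility
  a <- genDoseResponse(0.1, -1.3, c(0.01, 0.1, 1), 5, 0.05, seed = 2)
  b <- genDoseResponse(0.1, -1.3, c(0.01, 0.1, 1), 5, 0.05, seed = 2)
  expect_identical(a@responsePct, b@responsePct)
  expect_equal(length(a@responsePct), 15L)
})

test_that("energy-trace generator hits the requested moments", {
  subs <- c("p-L", "p*", "L(g)", "m-L", "m*")
  mq <- setNames(c(-60, -5, -2, -25, -3), subs)
  mv <- setNames(c(-120, -10, -5, -40, -8), subs)
  const <- genEnergyTraces(mq, mv, sd = 0, n = 50, seed = 1)
  expect_true(all(const[["p-L"]]$E_Q == -60))
  noisy <- genEnergyTraces(mq, mv, sd = 3, n = 2000, seed = 5)
  for (s in subs)
    expect_lt(abs(mean(noisy[[s]]$E_Q) - mq[[s]]), 3 * 3 / sqrt(2000))
  again <- genEnergyTraces(mq, mv, sd = 3, n = 2000, seed = 5)
  expect_identical(noisy, again)
  expect_error(genEnergyTraces(mq, mv, sd = -1), "non-negative")
})

test_that("lipid-frame generator is exact at zero jitter and isometry-invariant", {
  g <- genLipidFrames(zAxis(), rbind(c(5, 10)), dwellFrames = 120,
                      jitterSD = 0, seed = 1)
  expect_true(all(g$series@dP == 5))
  expect_true(all(g$series@dR2Cent == 10))
  # recomputed distances match the generated series
  d <- axisDistances(g$frames[[1]], zAxis())
  expect_equal(unname(d), c(5, 10), tolerance = 1e-9)
  # rigid rotation leaves recomputed distances unchanged
  set.seed(99)
  R <- randomRotation()
  fr <- g$frames[[1]]
  frRot <- coordinateFrame(fr@xyz %*% t(R), fr@masses, fr@tags)
  axRot <- principalAxisSmallestMoment(frRot)
  dRot <- axisDistances(frRot, axRot)
  expect_equal(unname(dRot), c(5, 10), tolerance = 1e-9)
  expect_error(genLipidFrames(zAxis(), rbind(c(5, 10), c(5, 10))),
               "distinct")
})

test_that("pH-trace generator maps pH through the inverse calibration", {
  cal <- boltzmannCalib()
  tr <- genPhTraces(6.3, cal, nh4clDeltaPH = 0, noiseCV = 0, seed = 1)
  r <- ratioSeries(tr)$ratio
  expect_true(all(abs(r - calibInverse(cal, 6.3)) < 1e-12))
  expect_equal(tr@stimulusOnsetS, 30)  # default onset convention
  expect_error(genPhTraces(12, cal), "outside the calibration domain")
})
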