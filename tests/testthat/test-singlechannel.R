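test_that("half-amplitude idealization recovers a noiseless square wave", {
  m <- twoStateGatingModel(10, 10, conductancePS = 60)
  ev <- eventSequence(rep(c("closed", "open"), 5), rep(c(40, 20), 5))
  tr <- renderTrace(ev, m, 90, noiseSdPA = 0, samplingKHz = 10)
  id <- idealize(tr, unitaryAmpPA = 5.4, deadTimeMS = 0)
  expect_identical(id@states, ev@states)
  expect_equal(id@durationsMS, ev@durationsMS, tolerance = 1e-9)
})

test_that("an all-baseline trace idealizes to a single closed event", {
  tr <- traceRecord(rep(0, 1000), samplingKHz = 10, holdingMV = 90)
  id <- idealize(tr, unitaryAmpPA = 5.4)
  expect_identical(id@states, "closed")
  expect_equal(id@totalMS, 100)
})

test_that("idealization of a noisy record recovers Po within 0.02", {
  m <- twoStateGatingModel(tauOpenMS = 26, tauClosedMS = 41)
  ev <- simulateGating(m, 90, 1.2e5, seed = 21)
  tr <- renderTrace(ev, m, 90, noiseSdPA = 0.54, samplingKHz = 10,
                    seed = 22)  # SNR 10
  id <- idealize(tr, unitaryAmpPA = 5.4, deadTimeMS = 0.3)
  expect_lt(abs(openProbability(id) - openProbability(ev)), 0.02)
})

test_that("a wrong-signed unitary amplitude warns and proceeds on magnitude", {
  m <- twoStateGatingModel(10, 10)
  ev <- eventSequence(c("closed", "open", "closed"), c(10, 10, 10))
  tr <- renderTrace(ev, m, -150, noiseSdPA = 0, samplingKHz = 10)
  expect_warning(id <- idealize(tr, unitaryAmpPA = +9), "sign")
  expect_error(idealize(tr, unitaryAmpPA = 0), "nonzero")
})

test_that("open probability counts time in conducting states", {
  expect_equal(openProbability(eventSequence("closed", 100)), 0)
  ev <- eventSequence(rep(c("closed", "open"), 10), rep(5, 20))
  expect_equal(openProbability(ev), 0.5)
  # sub counts as open by default, separately reportable
  ev2 <- eventSequence(c("closed", "open", "sub", "open"), c(10, 5, 3, 2))
  expect_equal(openProbability(ev2), 0.5)
  expect_equal(openProbability(ev2, countSubAsOpen = FALSE), 0.35)
  occ <- stateOccupancy(ev2)
  expect_equal(unname(occ["sub"]), 0.15)
})

test_that("dwell-time MLE equals the mean minus the dead time", {
  expect_equal(fitDwellExponential(c(2, 4, 6))@tauMS, 4)
  # left truncation: memorylessness gives tau = mean - d
  d <- 1.5
  x <- c(3, 5, 9) + d
  expect_equal(fitDwellExponential(x, deadTimeMS = d)@tauMS,
               mean(x) - d)
  expect_error(fitDwellExponential(5), "at least 2")
  expect_error(fitDwellExponential(c(1, 2), deadTimeMS = 1.5),
               "exceed the dead time")
})

test_that("dwell-time MLE is equivariant under time rescaling", {
  set.seed(3)
  x <- rexp(500, 1 / 80)
  f1 <- fitDwellExponential(x)
  f2 <- fitDwellExponential(7 * x)
  expect_equal(f2@tauMS, 7 * f1@tauMS, tolerance = 1e-12)
})

test_that("dwell fitting recovers the slow gating time constant at -150 mV", {
  # generating value: mean open dwell 421 ms
  set.seed(31)
  x <- rexp(5000, 1 / 421)
  f <- fitDwellExponential(x)
  expect_lt(abs(f@tauMS - 421), 3 * 421 / sqrt(5000))
})

test_that("the amplitude-histogram mixture recovers generator truth", {
  set.seed(41)
  x <- c(rnorm(7000, 0, 0.2), rnorm(3000, -3, 0.2))
  fit <- amplitudeHistogramFit(x, nComponents = 2, seed = 1)
  expect_equal(fit@means, c(-3, 0), tolerance = 0.05)
  expect_equal(fit@weights, c(0.3, 0.7), tolerance = 0.05)
  expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
  expect_gt(fit@separation, 10)
})

test_that("the EM mixture agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(43)
  x <- c(rnorm(1500, 0, 0.25), rnorm(1500, -2.5, 0.35))
  ours <- amplitudeHistogramFit(x, nComponents = 2, seed = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  oracleMeans <- sort(as.numeric(mc$parameters$mean))
  expect_equal(ours@means, oracleMeans, tolerance = 0.02)
})

test_that("a single-level trace yields one dominant mixture component", {
  fit <- amplitudeHistogramFit(rep(1.5, 500), nComponents = 2, seed = 1)
  expect_gte(max(fit@weights), 0.95)
  expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
})

test_that("polynomial unitary I-V fitting behaves as regression should", {
  v <- seq(-150, 90, by = 30)
  # linear data, degree 1: slope = g (pA/mV), intercept = -g*Erev
  g <- 0.06
  erev <- 10
  fit1 <- unitaryIVFit(v, g * (v - erev), degree = 1)
  expect_equal(fit1$coefficients, c(-g * erev, g), tolerance = 1e-9)
  # interpolating fit: zero residuals
  y <- c(1, -2, 5, 0)
  fitI <- unitaryIVFit(c(-1, 0, 1, 2), y, degree = 3)
  expect_lt(max(abs(fitI$residuals)), 1e-8)
  # cubic + noise: coefficient recovery within CI
  set.seed(5)
  beta <- c(0.5, 0.05, -1e-4, 2e-6)
  vv <- seq(-150, 100, by = 5)
  yy <- drop(outer(vv, 0:3, `^`) %*% beta) + rnorm(length(vv), sd = 0.05)
  fit3 <- unitaryIVFit(vv, yy, degree = 3)
  expect_equal(fit3$coefficients, beta, tolerance = 0.5)
  expect_error(unitaryIVFit(c(0, 1), c(0, 1), degree = 3),
               "underdetermined")
})

test_that("macroscopic reconstruction multiplies unitary current by Po", {
  v <- seq(-150, 100, by = 25)
  uiv <- unitaryIVFit(v, 0.05 * v, degree = 1)
  poOne <- data.frame(voltage_mV = v, po = 1)
  rec <- reconstructMacroscopic(uiv, poOne)
  expect_equal(rec$i_po, rec$i_pA, tolerance = 1e-9)
  # Po = 0 at 0 mV makes the product vanish there
  poU <- data.frame(voltage_mV = v, po = abs(v) / 150 * 0.5)
  rec2 <- reconstructMacroscopic(uiv, poU)
  expect_equal(rec2$i_po[rec2$voltage_mV == 0], 0)
  # asymmetric Po makes the product more rectifying than i alone
  poAsym <- data.frame(voltage_mV = v,
                       po = ifelse(v < 0, 0.3, 0.05))
  rec3 <- reconstructMacroscopic(uiv, poAsym)
  rectI <- rectificationIndex(
    data.frame(voltage_mV = v, i_pA = rec3$i_pA))
  expect_gt(attr(rec3, "rectification"), rectI)
  # commutes with current-axis scaling
  uiv2 <- unitaryIVFit(v, 2 * 0.05 * v, degree = 1)
  rec4 <- reconstructMacroscopic(uiv2, poAsym)
  expect_equal(rec4$i_po, 2 * rec3$i_po, tolerance = 1e-9)
})

test_that("the rectification index is the |I(-150)|/|I(+100)| ratio", {
  ohmic <- data.frame(voltage_mV = seq(-150, 100, 10),
                      i_pA = seq(-150, 100, 10))
  expect_equal(rectificationIndex(ohmic), 1.5)
  iv <- data.frame(voltage_mV = c(-150, 100), i_pA = c(-2.7, 1.0))
  expect_equal(rectificationIndex(iv), 2.7)
  iv2 <- transform(iv, i_pA = 2 * i_pA)
  expect_equal(rectificationIndex(iv2), 2.7)
  flat <- data.frame(voltage_mV = c(-150, 100), i_pA = c(-1, 0))
  expect_error(rectificationIndex(flat), "zero")
})
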