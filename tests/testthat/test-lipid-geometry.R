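test_that("the smallest-moment axis of a cylinder is its long axis", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  xyz <- cbind(cos(rep(th, 5)) * 8, sin(rep(th, 5)) * 8,
               rep(seq(-20, 20, by = 10), each = 12))
  fr <- coordinateFrame(xyz, tags = list(tmd = seq_len(nrow(xyz))))
  ax <- principalAxisSmallestMoment(fr)
  expect_equal(abs(sum(ax@direction * c(0, 0, 1))), 1, tolerance = 1e-12)
  expect_gte(ax@direction[3], 0)  # sign fixed toward +z
  expect_equal(ax@anchor, colMeans(xyz), tolerance = 1e-12)
})

test_that("the principal axis is equivariant under rigid rotations", {
  set.seed(61)
  # elongated random cloud
  xyz <- cbind(rnorm(80, sd = 2), rnorm(80, sd = 3), rnorm(80, sd = 12))
  m <- runif(80, 1, 16)
  fr <- coordinateFrame(xyz, m, tags = list(tmd = 1:80))
  ax <- principalAxisSmallestMoment(fr)
  for (i in 1:5) {
    R <- randomRotation()
    frR <- coordinateFrame(xyz %*% t(R), m, tags = list(tmd = 1:80))
    axR <- principalAxisSmallestMoment(frR)
    # directions match up to sign fixing
    expect_lt(min(sum((axR@direction - R %*% ax@direction)^2),
                  sum((axR@direction + R %*% ax@direction)^2)), 1e-18)
  }
})

test_that("the axis matches a brute-force inertia eigendecomposition", {
  set.seed(62)
  xyz <- cbind(rnorm(40, sd = 1), rnorm(40, sd = 2), rnorm(40, sd = 9))
  m <- runif(40, 1, 30)
  fr <- coordinateFrame(xyz, m, tags = list(tmd = 1:40))
  ax <- principalAxisSmallestMoment(fr)
  # naive per-atom tensor assembly as the independent oracle
  com <- colSums(xyz * m) / sum(m)
  I3 <- matrix(0, 3, 3)
  for (i in 1:40) {
    r <- xyz[i, ] - com
    I3 <- I3 + m[i] * (sum(r^2) * diag(3) - outer(r, r))
  }
  ev <- eigen(I3, symmetric = TRUE)
  vOracle <- ev$vectors[, which.min(ev$values)]
  if (vOracle[3] < 0) vOracle <- -vOracle
  expect_equal(ax@direction, vOracle, tolerance = 1e-9)
})

test_that("degenerate spherical selections are rejected", {
  # vertices of a cube: spherical inertia
  g <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  fr <- coordinateFrame(g, tags = list(tmd = 1:8))
  expect_error(principalAxisSmallestMoment(fr), "degenerate")
})

test_that("axis distances are perpendicular point-to-line distances", {
  fr <- coordinateFrame(rbind(c(0, 0, 5), c(3, 4, 17)),
                        masses = c(31, 12),
                        tags = list(phosphorus = 1L, r2_chain = 2L))
  d <- axisDistances(fr, zAxis())
  expect_equal(unname(d["dP"]), 0)          # on the axis
  expect_equal(unname(d["dR2Cent"]), 5)     # 3-4-5 triangle
  # translation along the axis changes nothing
  frT <- coordinateFrame(sweep(fr@xyz, 2, c(0, 0, -40), "-"),
                         fr@masses, fr@tags)
  expect_equal(axisDistances(frT, zAxis()), d, tolerance = 1e-12)
  frE <- coordinateFrame(fr@xyz, fr@masses, list(phosphorus = integer()))
  expect_error(axisDistances(frE, zAxis()), "phosphorus")
})

test_that("state histograms find exactly the generated modes", {
  # single tight cluster: one state at its center
  g1 <- genLipidFrames(zAxis(), rbind(c(6, 12)), dwellFrames = 400,
                       jitterSD = 0.2, seed = 71, makeFrames = FALSE)
  sm1 <- stateHistogram(g1$series)
  expect_identical(sm1@labels, "S1")
  expect_equal(sm1@centers[1, ], c(dP = 6, dR2Cent = 12), tolerance = 0.5)

  # seven separated centers; S1 must be the longest-dwelled one
  centers7 <- rbind(c(3, 5), c(3, 14), c(8, 5), c(8, 14), c(13, 9),
                    c(17, 17), c(20, 4))
  dwells <- c(1500, 400, 300, 500, 250, 200, 350)
  g7 <- genLipidFrames(zAxis(), centers7, dwellFrames = dwells,
                       jitterSD = 0.3, seed = 72, makeFrames = FALSE)
  sm7 <- stateHistogram(g7$series)
  expect_equal(length(sm7@labels), 7L)
  expect_equal(unname(sm7@centers[1, ]), centers7[1, ], tolerance = 0.5)
  expect_true(all(diff(sm7@populations) <= 0))
  # each generated center is matched by some mode within a bin width
  for (k in seq_len(7)) {
    dd <- sqrt((sm7@centers[, 1] - centers7[k, 1])^2 +
               (sm7@centers[, 2] - centers7[k, 2])^2)
    expect_lt(min(dd), 0.75)
  }

  # permuting the frame order changes nothing
  perm <- sample(length(g7$series@dP))
  sPerm <- new("AxisDistanceSeries", dP = g7$series@dP[perm],
               dR2Cent = g7$series@dR2Cent[perm], meta = list())
  smP <- stateHistogram(sPerm)
  expect_equal(smP@centers, sm7@centers)
  expect_equal(smP@populations, sm7@populations)
})

test_that("mode centers converge to generator centers as jitter shrinks", {
  centers <- rbind(c(5, 10), c(12, 18))
  for (jit in c(0.5, 0.2, 0.05)) {
    g <- genLipidFrames(zAxis(), centers, dwellFrames = 300,
                        jitterSD = jit, seed = 73, makeFrames = FALSE)
    sm <- stateHistogram(g$series)
    for (k in 1:2) {
      dd <- sqrt((sm@centers[, 1] - centers[k, 1])^2 +
                 (sm@centers[, 2] - centers[k, 2])^2)
      expect_lt(min(dd), 0.5)  # within one bin width
    }
  }
})

test_that("frame classification reports visit order and dwell totals", {
  # path S4 -> S3 -> S1 by construction: dwell ranks set the labels
  centers <- rbind(c(4, 6), c(10, 12), c(16, 20), c(22, 8))
  # dwells: state A longest (S1), then decreasing
  g <- genLipidFrames(zAxis(),
                      centers[c(4, 3, 1), ],      # visit order: 4th, 3rd, 1st
                      dwellFrames = c(150, 200, 800),
                      jitterSD = 0.2, seed = 74, makeFrames = FALSE)
  sm <- stateHistogram(g$series)
  expect_equal(length(sm@labels), 3L)
  cls <- classifyFrames(g$series, sm)
  expect_equal(sum(cls$dwellFrames), length(g$series@dP))
  expect_equal(cls$visitOrder[1], "S3")  # least populated visited first
  expect_equal(cls$visitOrder, c("S3", "S2", "S1"))
  expect_equal(cls$pathToS1, c("S3", "S2", "S1"))

  # frames exactly at the mode centers classify to their labels
  exact <- new("AxisDistanceSeries", dP = sm@centers[, 1],
               dR2Cent = sm@centers[, 2], meta = list())
  expect_identical(classifyFrames(exact, sm)$labels, sm@labels)
  # zero cutoff leaves everything unassigned
  cls0 <- classifyFrames(g$series, sm, cutoffA = 0)
  expect_true(all(cls0$labels == "unassigned"))
})
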