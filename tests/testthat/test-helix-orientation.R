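# Helix axis, tilt, torsion, circular summaries and histograms.

zGeometry <- methods::new("MembraneGeometry", midplane = c(0, 0, 0),
                          normal = c(0, 0, 1),
                          leafletOffsets = c(19, -19), frameTime = 0)

test_that("fitHelixAxis handles lines, helices and reversed order", {
  line <- cbind(0, 0, seq(0, 22) * 1.5)
  ax <- fitHelixAxis(line, 1:23)
  expect_equal(ax@axis, c(0, 0, 1))
  expect_equal(ax@rmsFit, 0, tolerance = 1e-9)

  helix <- buildIdealHelix(23)
  axC <- fitHelixAxis(helix$ca, 1:23)                  # curvature: exact
  expect_lt(acos(abs(axC@axis[3])) * 180 / pi, 1e-6)
  axS <- fitHelixAxis(helix$ca, 1:23, method = "svd")  # svd: small bias
  expect_lt(acos(abs(axS@axis[3])) * 180 / pi, 1)

  axRev <- fitHelixAxis(helix$ca[23:1, ], 1:23)
  expect_equal(axRev@axis, -axC@axis, tolerance = 1e-9)

  expect_error(fitHelixAxis(helix$ca[1:3, ], 1:3), "at least 4")
  expect_error(fitHelixAxis(matrix(1, 5, 3), 1:5), "degenerate")
})

test_that("tilt matches closed forms and is sign/rotation invariant", {
  mkAxis <- function(v) methods::new("HelixAxis", axis = v / sqrt(sum(v^2)),
                                     centroid = c(0, 0, 0),
                                     residueRange = c(1, 2), rmsFit = 0)
  expect_equal(tiltAngle(mkAxis(c(0, 0, 1)), zGeometry), 0)
  s30 <- c(sin(pi / 6), 0, cos(pi / 6))
  expect_equal(tiltAngle(mkAxis(s30), zGeometry), 30, tolerance = 1e-9)
  expect_equal(tiltAngle(mkAxis(c(1, 0, 0)), zGeometry), 90)
  # folding: axis and -axis give the same tilt
  expect_equal(tiltAngle(mkAxis(-s30), zGeometry),
               tiltAngle(mkAxis(s30), zGeometry))
  # invariance under rotation about the membrane normal
  set.seed(3)
  helix <- buildIdealHelix(23)$ca %*% t(rotationMatrixAxisAngle(c(0, 1, 0), 25))
  t0 <- tiltAngle(fitHelixAxis(helix, 1:23), zGeometry)
  for (ang in runif(5, 0, 360)) {
    rot <- helix %*% t(rotationMatrixAxisAngle(c(0, 0, 1), ang))
    expect_equal(tiltAngle(fitHelixAxis(rot, 1:23), zGeometry), t0,
                 tolerance = 1e-9)
  }
})

test_that("torsion matches cis/trans closed forms and the projection
          oracle on random quadruples", {
  expect_equal(torsionAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                            c(1, 1, 0)), 0)
  expect_equal(torsionAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                            c(1, -1, 0)), 180)
  set.seed(11)
  for (i in 1:1000) {
    q <- matrix(rnorm(12, sd = 3), 4, 3)
    ref <- torsionOracle(q[1, ], q[2, ], q[3, ], q[4, ])
    got <- torsionAngle(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_equal(got, ref, tolerance = 1e-9)
  }
  expect_error(torsionAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                            c(3, 1, 0)), "collinear")
  expect_error(torsionAngle(c(0, 1, 0), c(0, 1, 0), c(1, 0, 0),
                            c(1, 1, 0)), "coincide")
})

test_that("torsion is rigid-motion invariant and negates under mirror", {
  set.seed(5)
  for (i in 1:20) {
    q <- matrix(rnorm(12, sd = 3), 4, 3)
    ref <- torsionAngle(q[1, ], q[2, ], q[3, ], q[4, ])
    R <- rotationMatrixAxisAngle(rnorm(3), runif(1, 0, 360))
    shift <- rnorm(3)
    qr <- sweep(q %*% t(R), 2, shift, "+")
    expect_equal(torsionAngle(qr[1, ], qr[2, ], qr[3, ], qr[4, ]), ref,
                 tolerance = 1e-9)
    qm <- q %*% diag(c(1, 1, -1))   # mirror through z = 0
    got <- torsionAngle(qm[1, ], qm[2, ], qm[3, ], qm[4, ])
    if (abs(abs(ref) - 180) > 1e-6)
      expect_equal(got, -ref, tolerance = 1e-9)
  }
})

test_that("angle series wrap into their ranges and track frame counts", {
  # constant-tilt trajectory: identical values every frame
  sim <- simulateTrajectory(smallSpec(nFrames = 8, tiltMean = 30,
                                      tiltSD = 0, azimuthSD = 0,
                                      nWaters = 0))
  ts <- angleSeries(sim$trajectory, "tilt", caIndices = sim$roles$ca,
                    phosphorusIndices = sim$roles$phosphorus)
  expect_length(angleValues(ts), 8L)
  expect_equal(angleValues(ts), rep(30, 8), tolerance = 1e-9)

  # azimuth ramp 0 -> 350 wraps once into (-180, 180]
  ramp <- seq(0, 350, by = 10)
  frames <- lapply(ramp, function(a) {
    r <- a * pi / 180
    rbind(c(5, 0, -21), c(0, 0, -24), c(0, 0, -28),
          c(5 * cos(r), 5 * sin(r), -31))
  })
  tr <- makeTrajectory(frames, atomNames = rep("CA", 4))
  az <- angleSeries(tr, "azimuthal", quadIndices = 1:4)
  v <- angleValues(az)
  expect_true(all(v > -180 & v <= 180))
  expect_equal(sum(abs(diff(v)) > 100), 1L)  # single wrap discontinuity
})

test_that("summaries separate linear and circular statistics", {
  mkSeries <- function(v, kind = "azimuthal")
    methods::new("AngleSeries", times = seq_along(v), values = v,
                 kind = kind)
  s <- summarizeAngles(mkSeries(c(-10, 10)))  # 350 wrapped = -10
  expect_equal(s@circularMean, 0, tolerance = 1e-9)
  expect_equal(s@linearMean, 0)
  s2 <- summarizeAngles(mkSeries(c(170, -170)))  # wraps at the cut
  expect_equal(s2@circularMean, 180, tolerance = 1e-9)
  expect_equal(s2@linearMean, 0)  # linear mean misleading, by design

  s3 <- summarizeAngles(mkSeries(rep(27.6, 5), kind = "tilt"))
  expect_equal(s3@linearMean, 27.6)
  expect_equal(s3@linearSD, 0)
  expect_equal(s3@resultantLength, 1, tolerance = 1e-12)
  expect_false(s3@weaklyConcentrated)
})

test_that("circular mean recovers a von Mises location at n = 10,000", {
  set.seed(19)
  v <- rVonMises(10000, 30, vonMisesConcentration(7))
  s <- summarizeAngles(methods::new("AngleSeries",
                                    times = seq_along(v), values = v,
                                    kind = "azimuthal"))
  expect_lt(abs(s@circularMean - 30), 0.5)
  expect_lt(abs(s@circularSD - 7), 0.5)
  expect_lt(abs(s@linearSD - 7), 0.5)
})

test_that("uniform azimuth flags a weakly concentrated distribution", {
  set.seed(23)
  v <- rVonMises(1000, 0, 0)
  s <- summarizeAngles(methods::new("AngleSeries",
                                    times = seq_along(v), values = v,
                                    kind = "azimuthal"))
  expect_lt(s@resultantLength, 0.2)
  expect_true(s@weaklyConcentrated)
})

test_that("angle histograms cover the range and integrate to one", {
  set.seed(31)
  v <- rVonMises(20000, 0, 0)
  ser <- methods::new("AngleSeries", times = seq_along(v), values = v,
                      kind = "azimuthal")
  h <- angleHistogram(ser, binWidth = 10)
  expect_equal(nrow(h), 36L)
  expect_equal(sum(h$density) * 10, 1, tolerance = 1e-12)
  # uniform within 3 standard errors of 1/360 per degree
  p <- 10 / 360
  se <- sqrt(p * (1 - p) / 20000) / 10
  expect_true(all(abs(h$density - 1 / 360) < 3.5 * se))

  delta <- methods::new("AngleSeries", times = 1, values = 0,
                        kind = "azimuthal")
  hd <- angleHistogram(delta, binWidth = 10)
  expect_equal(sum(hd$count > 0), 1L)
  expect_equal(sum(hd$density) * 10, 1, tolerance = 1e-12)

  expect_error(angleHistogram(ser, binWidth = 7), "does not divide")
})
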