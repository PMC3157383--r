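# The generator itself: geometry of the ideal helix, determinism,
# conservation laws and quick recovery sanity checks.

test_that("the ideal helix has canonical alpha-helix geometry", {
  h <- buildIdealHelix(23)
  expect_equal(diff(range(h$ca[, 3])), 33)           # (23-1) x 1.5 A
  expect_equal(colMeans(h$ca), c(0, 0, 0), tolerance = 1e-12)
  caca <- sqrt(rowSums((h$ca[-1, ] - h$ca[-23, ])^2))
  expect_true(all(abs(caca - 3.8) < 0.2))
  cbDist <- sqrt(rowSums((h$cb - h$ca)^2))
  expect_equal(cbDist, rep(1.5, 23), tolerance = 1e-9)
  expect_error(buildIdealHelix(3), ">= 4")
})

test_that("degenerate distributions give constant angles", {
  sim <- simulateTrajectory(smallSpec(nFrames = 6, tiltMean = 0,
                                      tiltSD = 0, azimuthSD = 0,
                                      nWaters = 0))
  ts <- angleSeries(sim$trajectory, "tilt", caIndices = sim$roles$ca,
                    phosphorusIndices = sim$roles$phosphorus)
  expect_true(all(abs(angleValues(ts)) < 0.1))
})

test_that("identical seeds generate byte-identical files", {
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  g1 <- generateTrajectory(smallSpec(nFrames = 5, nWaters = 30), d1)
  g2 <- generateTrajectory(smallSpec(nFrames = 5, nWaters = 30), d2)
  expect_identical(unname(tools::md5sum(g1$trajectoryPath)),
                   unname(tools::md5sum(g2$trajectoryPath)))
  expect_identical(readLines(g1$topologyPath),
                   readLines(g2$topologyPath))
  g3 <- generateTrajectory(smallSpec(nFrames = 5, nWaters = 30,
                                     seed = 99), tempfile("gen3"))
  expect_false(identical(unname(tools::md5sum(g1$trajectoryPath)),
                         unname(tools::md5sum(g3$trajectoryPath))))
})

test_that("the generator leaves the caller's RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulateTrajectory(smallSpec(nFrames = 2, nWaters = 10)))
  expect_identical(.Random.seed, before)
})

test_that("water atom counts are conserved, penetration included", {
  spec <- smallSpec(nFrames = 30, nWaters = 40,
                    penetrationResidue = 505, penetrationProb = 0.4,
                    penetrationWaters = 3)
  sim <- simulateTrajectory(spec)
  expect_length(sim$roles$waters, 43L)  # 40 bulk + 3 reserved
  expect_length(sim$groundTruth$penetrationFrames, 30L)
  # on event frames the reserved waters sit within 4 A of the 505 CB
  cb505 <- selectAtoms(atomData(sim$trajectory), "CB", 505)
  ev <- which(sim$groundTruth$penetrationFrames)
  expect_gt(length(ev), 0L)
  for (f in ev[1:min(3, length(ev))]) {
    co <- frameCoords(sim$trajectory, f)
    pen <- sim$roles$waters[41:43]
    d <- sqrt(rowSums(sweep(co[pen, , drop = FALSE], 2,
                            co[cb505, ])^2))
    expect_true(all(d <= 4))
  }
  # over-filled boxes are refused
  expect_error(simulateTrajectory(smallSpec(nWaters = 50000)),
               "capacity")
})

test_that("penetration events create first-shell hydration at 505", {
  on <- simulateTrajectory(smallSpec(nFrames = 80, nWaters = 40,
                                     penetrationResidue = 505,
                                     penetrationProb = 0.3))
  off <- simulateTrajectory(smallSpec(nFrames = 80, nWaters = 40))
  cn <- function(sim) {
    cb <- selectAtoms(atomData(sim$trajectory), "CB", 505)
    rdf <- waterRDF(sim$trajectory, cb, sim$roles$waters, rMax = 8,
                    binWidth = 0.5)
    coordinationNumber(rdf, 4)
  }
  expect_gt(cn(on), 0)
  expect_equal(cn(off), 0)
})

test_that("analysis recovers generator tilt parameters (scaled run)", {
  spec <- smallSpec(nFrames = 2000, nWaters = 0, tiltMean = 27.6,
                    tiltSD = 7.0, seed = 41)
  sim <- simulateTrajectory(spec)
  s <- summarizeAngles(angleSeries(sim$trajectory, "tilt",
                                   caIndices = sim$roles$ca,
                                   phosphorusIndices =
                                     sim$roles$phosphorus))
  # the estimator is exact on the rigid helix: the series must match
  # the ground truth draw for draw
  expect_equal(s@linearMean, sim$groundTruth$expected$tiltMean,
               tolerance = 1e-6)
  expect_equal(s@linearSD, sim$groundTruth$expected$tiltSD,
               tolerance = 1e-6)
  # and the draw matches the requested distribution within sampling
  # error at n = 2000
  expect_lt(abs(s@linearMean - 27.6), 0.6)
  expect_lt(abs(s@linearSD - 7.0), 0.6)
})

test_that("azimuth ground truth round-trips through the torsion", {
  sim <- simulateTrajectory(smallSpec(nFrames = 50, azimuthMean = 40,
                                      azimuthSD = 15, nWaters = 0))
  az <- angleSeries(sim$trajectory, "azimuthal",
                    quadIndices = sim$roles$markers)
  expect_equal(angleValues(az), sim$groundTruth$azimuth,
               tolerance = 1e-9)
})

test_that("variant panels write one system per label plus a manifest", {
  specs <- list(
    WT = smallSpec(nFrames = 3, nWaters = 10, seed = 1),
    S505N = smallSpec(nFrames = 3, nWaters = 10, seed = 2),
    S505A = smallSpec(nFrames = 3, nWaters = 10, seed = 3),
    W515L = smallSpec(nFrames = 3, nWaters = 10, seed = 4),
    W515K = smallSpec(nFrames = 3, nWaters = 10, seed = 5,
                      azimuthUniform = TRUE))
  dir <- tempfile("panel")
  manifest <- makeVariantPanel(specs, dir)
  expect_length(manifest, 5L)
  for (lab in names(specs)) {
    expect_true(file.exists(file.path(dir, paste0(lab, ".pdb"))))
    expect_true(file.exists(file.path(dir, paste0(lab, ".dcd"))))
    expect_true(is.numeric(manifest[[lab]]$expected$tiltMean))
  }
  reread <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_setequal(names(reread), names(specs))
  expect_error(makeVariantPanel(specs[c(1, 1)], tempfile()),
               "duplicate")
  expect_error(makeVariantPanel(list(), tempfile()), "at least one")
})
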