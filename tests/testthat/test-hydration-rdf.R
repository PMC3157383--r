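# Minimum-image distances, RDF normalisation and coordination numbers.

test_that("minimum image wraps components into the nearest image", {
  expect_equal(minimumImageDistance(c(0, 0, 0), c(74, 0, 0),
                                    c(75, 75, 110)), 1)
  expect_equal(minimumImageDistance(c(1, 2, 3), c(1, 2, 3),
                                    c(20, 20, 20)), 0)
  set.seed(13)
  for (i in 1:200) {
    p <- runif(3, 0, 20); q <- runif(3, 0, 20); box <- c(20, 20, 20)
    expect_equal(minimumImageDistance(p, q, box),
                 miDistanceBruteForce(p, q, box), tolerance = 1e-9)
  }
})

# uniform "ideal gas" water trajectory around a fixed centre atom
idealGasTrajectory <- function(nFrames, nWaters, box, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(nFrames), function(f)
    rbind(c(0, 0, 0),
          cbind(runif(nWaters, -box[1] / 2, box[1] / 2),
                runif(nWaters, -box[2] / 2, box[2] / 2),
                runif(nWaters, -box[3] / 2, box[3] / 2))))
  makeTrajectory(frames, atomNames = c("CB", rep("OH2", nWaters)),
                 box = box)
}

test_that("binned g(r) equals the brute-force pair-count oracle", {
  tr <- idealGasTrajectory(3, 50, c(24, 24, 24), seed = 5)
  rdf <- waterRDF(tr, 1, 2:51, rMax = 10, binWidth = 1)
  oracle <- rdfCountsBruteForce(tr, 1, 2:51, rMax = 10, binWidth = 1)
  expect_identical(as.numeric(rdf@pairCounts), as.numeric(oracle))
  # and the g normalisation is counts / (frames * rho * shell volume)
  rho <- 50 / prod(c(24, 24, 24))
  edges <- 0:10
  shells <- 4 / 3 * pi * diff(edges^3)
  expect_equal(rdf@gValues, oracle / 3 / (rho * shells),
               tolerance = 1e-12)
})

test_that("ideal-gas g(r) is 1 within 3 standard errors beyond 2 A", {
  box <- c(40, 40, 40)
  tr <- idealGasTrajectory(200, 300, box, seed = 8)
  rdf <- waterRDF(tr, 1, 2:301, rMax = 10, binWidth = 0.5)
  rho <- 300 / prod(box)
  edges <- rdf@binEdges
  mids <- edges[-1] - 0.25
  lambda <- rho * 4 / 3 * pi * diff(edges^3)   # mean count/frame/bin
  se <- 1 / sqrt(lambda * rdf@nFrames)
  sel <- mids > 2
  expect_true(all(abs(rdf@gValues[sel] - 1) < 3 * se[sel]))
})

test_that("pair counts are conserved against a direct recount", {
  sim <- simulateTrajectory(smallSpec(nFrames = 6, nWaters = 80))
  r <- sim$roles
  cb505 <- selectAtoms(atomData(sim$trajectory), "CB", 505)
  rdf <- waterRDF(sim$trajectory, cb505, r$waters, rMax = 15,
                  binWidth = 0.5)
  direct <- 0
  for (f in 1:6) {
    co <- frameCoords(sim$trajectory, f)
    d <- apply(co[r$waters, ], 1, function(w)
      miDistanceBruteForce(co[cb505, ], w, c(75, 75, 110)))
    direct <- direct + sum(d < 15)
  }
  expect_equal(sum(rdf@pairCounts), direct)
})

test_that("coordination numbers follow the closed ideal-gas form", {
  box <- c(40, 40, 40)
  tr <- idealGasTrajectory(150, 300, box, seed = 21)
  rdf <- waterRDF(tr, 1, 2:301, rMax = 10, binWidth = 0.5)
  expect_equal(coordinationNumber(rdf, 0), 0)
  expect_equal(coordinationNumber(rdf, 10),
               sum(rdf@pairCounts) / rdf@nFrames)
  rho <- 300 / prod(box)
  expected5 <- rho * 4 / 3 * pi * 125
  got5 <- coordinationNumber(rdf, 5)
  expect_lt(abs(got5 - expected5),
            3 * sqrt(expected5 / rdf@nFrames))
  # monotone non-decreasing in the cutoff
  cuts <- seq(0.5, 10, 0.5)
  cn <- vapply(cuts, function(rc) coordinationNumber(rdf, rc), 0)
  expect_true(all(diff(cn) >= 0))
  expect_error(coordinationNumber(rdf, 12), "exceeds")
})

test_that("buried centres see less water than interfacial centres", {
  sim <- simulateTrajectory(smallSpec(nFrames = 15, nWaters = 400,
                                      tiltMean = 0, tiltSD = 0))
  topo <- atomData(sim$trajectory)
  w <- sim$roles$waters
  buried <- selectAtoms(topo, "CB", 501)     # slab middle
  interf <- selectAtoms(topo, "CB", 512)     # near the phosphate plane
  rdfB <- waterRDF(sim$trajectory, buried, w, rMax = 12, binWidth = 0.5)
  rdfI <- waterRDF(sim$trajectory, interf, w, rMax = 12, binWidth = 0.5)
  expect_lt(coordinationNumber(rdfB, 12), coordinationNumber(rdfI, 12))
  expect_equal(coordinationNumber(rdfB, 4), 0)  # no penetration events
})

test_that("RDF input validation guards the minimum-image assumptions", {
  tr <- idealGasTrajectory(2, 20, c(24, 24, 24))
  expect_error(waterRDF(tr, 1, integer()), "empty water selection")
  expect_error(waterRDF(tr, 1, 2:21, rMax = 13), "half the smallest")
  # no box: falls back to non-periodic distances with a message
  trNoBox <- makeTrajectory(frameCoords(tr, 1),
                            atomNames = c("CB", rep("OH2", 20)))
  expect_message(waterRDF(trNoBox, 1, 2:21, rMax = 10), "non-periodic")
})

test_that("plateau normalisation rescales the far field to one", {
  tr <- idealGasTrajectory(100, 300, c(40, 40, 40), seed = 30)
  rdf <- waterRDF(tr, 1, 2:301, rMax = 10, binWidth = 0.5,
                  normalization = "plateau")
  outer <- rdf@gValues[rdf@binEdges[-1] > 8]
  expect_equal(mean(outer), 1, tolerance = 1e-9)
})
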