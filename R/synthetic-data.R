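# Synthetic helix-in-bilayer trajectory generator with known ground
# truth. Every frame is drawn independently from the configured angular
# distributions; the helix is rigid, so the orientation estimators are
# exercised in isolation from conformational noise.

#' Construct a SyntheticSpec
#'
#' Defaults describe a single-pass TM helix of 23 residues (numbered
#' from 490) spanning a phosphate-plane slab at +/-19 Angstrom inside a
#' 75 x 75 x 110 Angstrom box, sampled for 10,000 frames at 10 ps with
#' a von Mises tilt of mean 27.6 and SD 7.0 degrees. Water oxygens are
#' placed uniformly outside the slab; 500 of them keep the desk-scale
#' system light (density only rescales RDF normalisation, never the
#' angle observables).
#'
#' @param nFrames,dt frame count and spacing (ps).
#' @param helixResidues,residueNumberStart helix length and first
#'   residue number.
#' @param tiltMean,tiltSD tilt distribution (degrees); SD 0 = constant.
#' @param azimuthMean,azimuthSD azimuth distribution (degrees).
#' @param azimuthUniform TRUE for a uniform azimuth on (-180, 180].
#' @param slabHalfThickness phosphate-plane distance from the midplane.
#' @param box orthorhombic edge lengths (Angstrom).
#' @param nWaters bulk water oxygens per frame.
#' @param nPhosphorus phosphorus pseudo-atoms (half per leaflet).
#' @param penetrationResidue residue receiving rare water-penetration
#'   events (NA disables).
#' @param penetrationProb per-frame event probability.
#' @param penetrationWaters waters moved to the residue per event.
#' @param icMode Box1 placement, \code{"open"} or \code{"packed"}.
#' @param seed RNG seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nFrames = 10000, dt = 10,
                          helixResidues = 23, residueNumberStart = 490,
                          tiltMean = 27.6, tiltSD = 7.0,
                          azimuthMean = 0, azimuthSD = 20,
                          azimuthUniform = FALSE,
                          slabHalfThickness = 19,
                          box = c(75, 75, 110),
                          nWaters = 500, nPhosphorus = 60,
                          penetrationResidue = NA, penetrationProb = 0,
                          penetrationWaters = 3,
                          icMode = "open", seed = 1) {
  methods::new("SyntheticSpec",
               nFrames = as.integer(nFrames), dt = dt,
               helixResidues = as.integer(helixResidues),
               residueNumberStart = as.integer(residueNumberStart),
               tiltMean = tiltMean, tiltSD = tiltSD,
               azimuthMean = azimuthMean, azimuthSD = azimuthSD,
               azimuthUniform = azimuthUniform,
               slabHalfThickness = slabHalfThickness,
               box = as.numeric(box),
               nWaters = as.integer(nWaters),
               nPhosphorus = as.integer(nPhosphorus),
               penetrationResidue = as.numeric(penetrationResidue),
               penetrationProb = penetrationProb,
               penetrationWaters = as.integer(penetrationWaters),
               icMode = icMode, seed = as.integer(seed))
}

#' Build an ideal alpha-helix (Calpha and Cbeta per residue)
#'
#' Canonical geometry along +z: Calpha on a 2.3 Angstrom radius,
#' 1.5 Angstrom rise and 100 degrees twist per residue; Cbeta displaced
#' 1.5 Angstrom radially outward from its Calpha. The Calpha centroid
#' sits at the origin.
#'
#' @param nResidues number of residues (>= 4).
#' @return list with matrices \code{ca} and \code{cb}
#'   (\code{nResidues x 3}, Angstrom).
#' @export
buildIdealHelix <- function(nResidues) {
  if (nResidues < 4L) stop("nResidues must be >= 4")
  i <- seq_len(nResidues) - 1
  phase <- .rad(100 * i)
  ca <- cbind(2.3 * cos(phase), 2.3 * sin(phase), 1.5 * i)
  cb <- cbind(3.8 * cos(phase), 3.8 * sin(phase), 1.5 * i)
  centroid <- colMeans(ca)
  list(ca = sweep(ca, 2, centroid), cb = sweep(cb, 2, centroid))
}

# Topology table for a spec; attr "roles" gives index groups.
.syntheticTopology <- function(spec) {
  n <- spec@helixResidues
  resno0 <- spec@residueNumberStart
  nPen <- if (.penetrationEnabled(spec)) spec@penetrationWaters else 0L
  nW <- spec@nWaters + nPen
  prot <- data.frame(
    atomName = rep(c("CA", "CB"), n),
    residueNumber = rep(resno0 + seq_len(n) - 1L, each = 2L),
    residueName = "ALA", segmentId = "PROT", element = "C")
  icm <- data.frame(atomName = "CA", residueNumber = 1:4,
                    residueName = "GLY", segmentId = "ICM", element = "C")
  box1 <- data.frame(atomName = "CA", residueNumber = 50:53,
                     residueName = "GLY", segmentId = "ICD", element = "C")
  memb <- data.frame(atomName = "P",
                     residueNumber = seq_len(spec@nPhosphorus),
                     residueName = "POP", segmentId = "MEMB",
                     element = "P")
  wat <- if (nW > 0L)
    data.frame(atomName = "OH2", residueNumber = seq_len(nW),
               residueName = "HOH", segmentId = "WAT", element = "O")
    else NULL
  topo <- rbind(prot, icm, box1, memb, wat)
  topo <- cbind(atomIndex = seq_len(nrow(topo)), topo)
  attr(topo, "box") <- spec@box
  roles <- list(
    ca = which(topo$segmentId == "PROT" & topo$atomName == "CA"),
    cb = which(topo$segmentId == "PROT" & topo$atomName == "CB"),
    markers = which(topo$segmentId == "ICM"),
    box1 = which(topo$segmentId == "ICD"),
    phosphorus = which(topo$segmentId == "MEMB"),
    waters = which(topo$segmentId == "WAT"))
  attr(topo, "roles") <- roles
  topo
}

.penetrationEnabled <- function(spec) {
  !is.na(spec@penetrationResidue) && spec@penetrationProb > 0 &&
    spec@penetrationWaters > 0L
}

# IC marker positions for one azimuth angle (degrees). m2 and m3 lie on
# the bilayer normal, m1 is the fixed reference arm and m4 the rotating
# arm, so torsion(m1, m2, m3, m4) equals the azimuth exactly and is 0
# at the reference orientation.
.markerPositions <- function(azimuthDeg, slab) {
  a <- .rad(azimuthDeg)
  rbind(c(5, 0, -(slab + 2)),
        c(0, 0, -(slab + 5)),
        c(0, 0, -(slab + 9)),
        c(5 * cos(a), 5 * sin(a), -(slab + 12)))
}

.box1Positions <- function(mode, slab) {
  zB <- if (mode == "open") -(slab + 7) else -(slab - 5)
  cbind(10 + c(-1, 1, 1, -1), 10 + c(-1, -1, 1, 1), zB)
}

#' Generate a synthetic trajectory in memory
#'
#' Per frame: sample tilt and azimuth, rotate the rigid ideal helix
#' about the bilayer centre (\code{Rz(azimuth) Ry(tilt)}), jitter the
#' phosphorus pseudo-planes, place water oxygens uniformly outside the
#' slab, position the four IC torsion markers so that their torsion
#' equals the sampled azimuth, and (on penetration events) move the
#' reserved penetration waters to within 4 Angstrom of the target
#' residue's Cbeta. Fully reproducible from \code{spec@seed}; the
#' caller's RNG state is left untouched.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{trajectory} (a \linkS4class{Trajectory}),
#'   \code{groundTruth} (per-frame sampled \code{tilt} and
#'   \code{azimuth} in degrees, logical \code{penetrationFrames}, and
#'   \code{expected} summary statistics) and \code{roles} (named atom
#'   index groups: ca, cb, markers, box1, phosphorus, waters).
#' @export
simulateTrajectory <- function(spec) {
  methods::validObject(spec)
  slab <- spec@slabHalfThickness
  bx <- spec@box
  if (slab >= bx[3] / 2)
    stop("slabHalfThickness must be smaller than half the z box edge")
  nPen <- if (.penetrationEnabled(spec)) spec@penetrationWaters else 0L
  nWtot <- spec@nWaters + nPen
  outsideVol <- bx[1] * bx[2] * (bx[3] - 2 * slab)
  if (nWtot > outsideVol / 2.8^3)
    stop(sprintf(
      "%d waters exceed box capacity at 2.8 A minimum separation (~%d)",
      nWtot, floor(outsideVol / 2.8^3)))
  topo <- .syntheticTopology(spec)
  roles <- attr(topo, "roles")
  helix <- buildIdealHelix(spec@helixResidues)
  nf <- spec@nFrames
  na <- nrow(topo)

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
            assign(".Random.seed", oldSeed, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(spec@seed)

  # fixed phosphorus xy, half per leaflet
  nP <- spec@nPhosphorus
  nUp <- nP %/% 2L
  pXY <- cbind(stats::runif(nP, -bx[1] / 2, bx[1] / 2),
               stats::runif(nP, -bx[2] / 2, bx[2] / 2))
  pSign <- rep(c(1, -1), c(nUp, nP - nUp))

  tilt <- if (spec@tiltSD == 0) rep(spec@tiltMean, nf)
          else rVonMises(nf, spec@tiltMean,
                         vonMisesConcentration(spec@tiltSD))
  azimuth <- if (spec@azimuthUniform)
    wrapAngle(stats::runif(nf, -180, 180))
  else if (spec@azimuthSD == 0) rep(wrapAngle(spec@azimuthMean), nf)
  else rVonMises(nf, spec@azimuthMean,
                 vonMisesConcentration(spec@azimuthSD))
  pJitter <- matrix(stats::rnorm(nP * nf, 0, 0.8), nP, nf)
  penFrames <- if (nPen > 0L) stats::runif(nf) < spec@penetrationProb
               else rep(FALSE, nf)

  protIdx <- sort(c(roles$ca, roles$cb))  # interleaved CA/CB rows
  helix0 <- matrix(0, length(protIdx), 3L)
  helix0[match(roles$ca, protIdx), ] <- helix$ca
  helix0[match(roles$cb, protIdx), ] <- helix$cb
  box1Pos <- .box1Positions(spec@icMode, slab)
  penTargetRow <- if (nPen > 0L)
    which(topo$residueNumber[roles$cb] == spec@penetrationResidue)
  else integer()
  if (nPen > 0L && !length(penTargetRow))
    stop("penetrationResidue ", spec@penetrationResidue,
         " is not a helix residue")

  coords <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf)) {
    M <- .rotZ(azimuth[f]) %*% .rotY(tilt[f])
    coords[protIdx, , f] <- helix0 %*% t(M)
    coords[roles$markers, , f] <- .markerPositions(azimuth[f], slab)
    coords[roles$box1, , f] <- box1Pos
    coords[roles$phosphorus, , f] <-
      cbind(pXY, pSign * slab + pJitter[, f])
    if (nWtot > 0L) {
      w <- cbind(stats::runif(nWtot, -bx[1] / 2, bx[1] / 2),
                 stats::runif(nWtot, -bx[2] / 2, bx[2] / 2),
                 .sampleOutsideSlab(nWtot, slab, bx[3]))
      if (nPen > 0L && penFrames[f]) {
        cbPos <- coords[roles$cb[penTargetRow[1]], , f]
        w[spec@nWaters + seq_len(nPen), ] <- .sampleNear(nPen, cbPos, 3.5)
      }
      coords[roles$waters, , f] <- w
    }
  }
  traj <- newTrajectory(topo, coords, box = bx, dt = spec@dt)
  tiltApplied <- abs(tilt)   # the measured tilt folds to [0, 90]
  csA <- circularStats(azimuth)
  gt <- list(
    tilt = tilt, azimuth = azimuth, penetrationFrames = penFrames,
    expected = list(
      tiltMean = mean(tiltApplied), tiltSD = stats::sd(tiltApplied),
      azimuthCircularMean = csA$mean,
      azimuthResultantLength = csA$R,
      nFrames = nf))
  list(trajectory = traj, groundTruth = gt, roles = roles)
}

# z uniform over [-bz/2, -slab) U (slab, bz/2]
.sampleOutsideSlab <- function(n, slab, bz) {
  z <- -bz / 2 + stats::runif(n) * (bz - 2 * slab)
  z + ifelse(z > -slab, 2 * slab, 0)
}

# uniform in a sphere of radius rMax around p
.sampleNear <- function(n, p, rMax) {
  u <- matrix(stats::rnorm(3 * n), n, 3L)
  u <- u / sqrt(rowSums(u^2))
  r <- rMax * stats::runif(n)^(1 / 3)
  sweep(u * r, 2, p, "+")
}

#' Generate a synthetic system on disk
#'
#' Writes a PDB topology (first-frame coordinates plus CRYST1), a DCD
#' trajectory and a ground-truth JSON next to each other.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param outDir output directory (created if needed).
#' @param prefix file name prefix.
#' @return list with \code{topologyPath}, \code{trajectoryPath},
#'   \code{groundTruthPath}, \code{groundTruth} and \code{roles}.
#' @export
generateTrajectory <- function(spec, outDir, prefix = "system") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateTrajectory(spec)
  topologyPath <- file.path(outDir, paste0(prefix, ".pdb"))
  trajectoryPath <- file.path(outDir, paste0(prefix, ".dcd"))
  gtPath <- file.path(outDir, paste0(prefix, "_groundtruth.json"))
  writeTopologyPDB(sim$trajectory, topologyPath)
  writeTrajectoryDCD(sim$trajectory, trajectoryPath)
  jsonlite::write_json(
    list(expected = sim$groundTruth$expected,
         seed = spec@seed, nFrames = spec@nFrames, dt = spec@dt),
    gtPath, auto_unbox = TRUE, digits = NA)
  list(topologyPath = topologyPath, trajectoryPath = trajectoryPath,
       groundTruthPath = gtPath, groundTruth = sim$groundTruth,
       roles = sim$roles)
}

#' Generate a labelled panel of synthetic variant systems
#'
#' One topology + trajectory pair per label, plus a JSON manifest with
#' each system's ground-truth summary (the reference for recovery
#' checks).
#'
#' @param specs named list of \linkS4class{SyntheticSpec} objects;
#'   names are the variant labels and must be unique.
#' @param outDir output directory.
#' @return the manifest as a list, invisibly; written to
#'   \code{manifest.json} in \code{outDir}.
#' @export
makeVariantPanel <- function(specs, outDir) {
  if (!length(specs)) stop("need at least one labelled spec")
  labels <- names(specs)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("every spec must be labelled (named)")
  if (anyDuplicated(labels))
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (lab in labels) {
    g <- generateTrajectory(specs[[lab]], outDir, prefix = lab)
    manifest[[lab]] <- list(
      topology = basename(g$topologyPath),
      trajectory = basename(g$trajectoryPath),
      dt = specs[[lab]]@dt,
      expected = g$groundTruth$expected)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
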