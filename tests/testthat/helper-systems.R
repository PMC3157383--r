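# Small system builders used across test files.

# A desk-scale spec: few frames, few waters, otherwise defaults.
smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(nFrames = 50, nWaters = 60, seed = 7)
  do.call(syntheticSpec, utils::modifyList(defaults, args))
}

# Reference-orientation system: helix along the normal, azimuth 0.
referenceSpec <- function(...) {
  smallSpec(nFrames = 1, tiltMean = 0, tiltSD = 0,
            azimuthMean = 0, azimuthSD = 0, nWaters = 20, ...)
}

# Minimal topology data.frame for hand-built trajectories.
makeTopology <- function(atomNames, resno = seq_along(atomNames),
                         resid = "ALA", segid = "PROT", element = "C") {
  data.frame(atomIndex = seq_along(atomNames), atomName = atomNames,
             residueNumber = resno, residueName = resid,
             segmentId = segid, element = element,
             stringsAsFactors = FALSE)
}

# Trajectory holding arbitrary per-frame coordinate matrices.
makeTrajectory <- function(frames, atomNames = NULL, box = NULL,
                           dt = 10, ...) {
  if (is.matrix(frames)) frames <- list(frames)
  na <- nrow(frames[[1]])
  if (is.null(atomNames)) atomNames <- rep("CA", na)
  coords <- array(NA_real_, c(na, 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  newTrajectory(makeTopology(atomNames, ...), coords, box = box, dt = dt)
}

# Phosphorus slab frame: two jittered planes at +/- half thickness.
slabCoords <- function(nP = 20, half = 19, jitter = 0, seed = 1) {
  set.seed(seed)
  xy <- matrix(runif(2 * nP, -30, 30), nP, 2)
  z <- rep(c(half, -half), each = nP / 2) + rnorm(nP, 0, jitter)
  cbind(xy, z)
}
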