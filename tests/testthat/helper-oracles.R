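# Independent oracles, deliberately computed by different routes than
# the package implementation.

# Dihedral via projections onto the plane perpendicular to the central
# bond (the implementation uses the two plane normals + atan2).
torsionOracle <- function(p1, p2, p3, p4) {
  b <- p3 - p2; b <- b / sqrt(sum(b^2))
  u <- p1 - p2; w <- p4 - p3
  uP <- u - sum(u * b) * b
  wP <- w - sum(w * b) * b
  crossUW <- c(uP[2] * wP[3] - uP[3] * wP[2],
               uP[3] * wP[1] - uP[1] * wP[3],
               uP[1] * wP[2] - uP[2] * wP[1])
  ang <- -atan2(sum(b * crossUW), sum(uP * wP)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Minimum-image distance by exhaustive search over the 27 image
# translates.
miDistanceBruteForce <- function(p, q, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- p - (q + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# Direct per-frame recount of RDF pair counts (no shared binning code).
rdfCountsBruteForce <- function(trajectory, centerIndex, waterIndices,
                                rMax, binWidth) {
  nb <- ceiling(rMax / binWidth - 1e-9)
  counts <- numeric(nb)
  hasBox <- nrow(boxDims(trajectory)) > 0L
  for (f in seq_len(nFrames(trajectory))) {
    co <- frameCoords(trajectory, f)
    box <- if (hasBox) boxDims(trajectory)[f, ] else c(Inf, Inf, Inf)
    for (wi in waterIndices) {
      d <- miDistanceBruteForce(co[centerIndex, ], co[wi, ], box)
      if (d < rMax) {
        b <- min(nb, floor(d / binWidth) + 1L)
        counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

rotationMatrixAxisAngle <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2)); t <- deg * pi / 180
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}
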