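# Water-residue radial distribution functions with minimum-image
# periodic distances, and hydration-shell coordination numbers.

#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' Euclidean distance after wrapping each Cartesian component of the
#' separation into [-edge/2, edge/2].
#'
#' @param p,q numeric 3-vectors (Angstrom).
#' @param box orthorhombic edge lengths (3-vector, Angstrom).
#' @return distance in Angstrom.
#' @export
minimumImageDistance <- function(p, q, box) {
  if (any(box <= 0)) stop("box edges must be > 0")
  d <- p - q
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# Vectorised: distances from one point to each row of Q.
.miDistMany <- function(p, Q, box = NULL) {
  d <- sweep(Q, 2, p)
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  sqrt(rowSums(d^2))
}

#' Water radial distribution function around a centre atom
#'
#' For each frame, minimum-image distances from the centre atom (a
#' residue's Cbeta in the intended use) to every water oxygen are
#' binned on a uniform grid from 0 to \code{rMax}. The RDF is
#' \deqn{g(r) = \frac{\langle n(r) \rangle}{\rho \, V_{shell}(r)}}
#' with shell volume \eqn{4\pi/3 (r_2^3 - r_1^3)}.
#'
#' Normalisation modes: \code{"box"} uses the overall water number
#' density (waters / box volume) as \eqn{\rho}; in membrane systems the
#' far-field plateau then sits below 1 because the slab excludes water.
#' \code{"plateau"} rescales g so that its mean over the outer 20\% of
#' bins equals 1, which eases cross-variant shape comparison.
#'
#' Frames without box information fall back to non-periodic distances
#' (reported via a message).
#'
#' @param trajectory a (windowed/strided) \linkS4class{Trajectory}.
#' @param centerIndex atom index of the centre atom.
#' @param waterIndices atom indices of the water oxygens (non-empty).
#' @param rMax histogram range (Angstrom); must not exceed half the
#'   smallest box edge.
#' @param binWidth bin width (Angstrom).
#' @param normalization \code{"box"} or \code{"plateau"}.
#' @param centerLabel descriptor stored in the result.
#' @return an \linkS4class{RDFResult}.
#' @export
waterRDF <- function(trajectory, centerIndex, waterIndices,
                     rMax = 15, binWidth = 0.1,
                     normalization = c("box", "plateau"),
                     centerLabel = sprintf("atom %d", centerIndex)) {
  normalization <- match.arg(normalization)
  if (!length(waterIndices)) stop("empty water selection")
  if (length(centerIndex) != 1L) stop("centerIndex must be one atom")
  nf <- nFrames(trajectory)
  hasBox <- nrow(trajectory@box) > 0L
  if (hasBox) {
    minEdge <- min(trajectory@box)
    if (rMax > minEdge / 2 + 1e-9)
      stop(sprintf(
        "rMax %g A exceeds half the smallest box edge (%g A): %s",
        rMax, minEdge / 2, "minimum-image convention violated"))
  } else {
    message("no box information: computing non-periodic distances")
  }
  nb <- ceiling(rMax / binWidth - 1e-9)
  edges <- binWidth * (0:nb)
  counts <- numeric(nb)
  volAcc <- 0
  for (f in seq_len(nf)) {
    co <- trajectory@coords[, , f]
    box <- if (hasBox) trajectory@box[f, ] else NULL
    d <- .miDistMany(co[centerIndex, ], co[waterIndices, , drop = FALSE],
                     box)
    d <- d[d < rMax]
    if (length(d)) {
      bin <- pmin(nb, floor(d / binWidth) + 1L)
      counts <- counts + tabulate(bin, nbins = nb)
    }
    volAcc <- volAcc + if (hasBox) prod(box) else NA_real_
  }
  refDensity <- if (hasBox) length(waterIndices) / (volAcc / nf)
                else length(waterIndices) / (4 / 3 * pi * rMax^3)
  shellVol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  g <- (counts / nf) / (refDensity * shellVol)
  if (normalization == "plateau") {
    outer <- g[seq.int(ceiling(0.8 * nb) + 1L, nb)]
    plateau <- mean(outer)
    if (!is.finite(plateau) || plateau <= 0)
      stop("cannot plateau-normalise: no pairs in the outer 20% of bins")
    g <- g / plateau
    refDensity <- refDensity * plateau
  }
  methods::new("RDFResult", binEdges = edges, gValues = g,
               pairCounts = counts, referenceDensity = refDensity,
               nFrames = as.integer(nf), centerLabel = centerLabel,
               normalization = normalization)
}

#' Mean number of waters within a cutoff of the RDF centre
#'
#' Sum of the raw pair counts in the bins entirely below \code{rCut},
#' divided by the number of frames. Monotone non-decreasing in
#' \code{rCut}.
#'
#' @param rdf an \linkS4class{RDFResult}.
#' @param rCut cutoff radius (Angstrom), at most the RDF range.
#' @return mean water count (waters/frame).
#' @export
coordinationNumber <- function(rdf, rCut) {
  rMax <- max(rdf@binEdges)
  if (rCut > rMax + 1e-9)
    stop(sprintf("rCut %g A exceeds the RDF range %g A", rCut, rMax))
  keep <- rdf@binEdges[-1] <= rCut + 1e-9
  sum(rdf@pairCounts[keep]) / rdf@nFrames
}
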