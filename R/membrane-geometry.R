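# Bilayer frame estimation from lipid phosphorus atoms, and signed
# depth along the membrane normal.

#' Estimate the bilayer midplane, normal and leaflet planes
#'
#' In \code{"fixed-z"} mode (default; appropriate when the system was
#' built with the bilayer normal along the lab z axis) the normal is
#' (0, 0, 1) and the midplane sits at the mean phosphorus z. In
#' \code{"fitted"} mode the normal is refined iteratively: leaflets are
#' split by the sign of the projection onto the current normal, each
#' leaflet's centroid is subtracted (folding the bilayer onto one
#' plane), and the normal is re-estimated as the smallest principal
#' component of the folded coordinates. A plain smallest-PC of the raw
#' coordinates would fail here, because the leaflet separation itself
#' dominates the variance. The iteration starts from the direction
#' toward \code{extracellularPoint} when given, else from the lab z
#' axis, so fitted mode handles membranes tilted arbitrarily far when
#' an orientation hint is supplied, and up to roughly 45 degrees
#' without one. Leaflet offsets are the mean projections of each side.
#'
#' The normal is oriented so that \code{extracellularPoint} (when given)
#' lies on its positive side; otherwise toward +z.
#'
#' @param coords frame coordinate matrix (\code{\link{frameCoords}}).
#' @param phosphorusIndices atom indices of the lipid phosphorus atoms
#'   (>= 6, both leaflets represented).
#' @param mode \code{"fixed-z"} or \code{"fitted"}.
#' @param extracellularPoint optional 3-vector on the extracellular side
#'   (e.g. the Calpha of the first, most extracellular TM residue).
#' @param frameTime time attached to the returned geometry (ps).
#' @return a \linkS4class{MembraneGeometry}.
#' @export
estimateMembraneGeometry <- function(coords, phosphorusIndices,
                                     mode = c("fixed-z", "fitted"),
                                     extracellularPoint = NULL,
                                     frameTime = 0) {
  mode <- match.arg(mode)
  if (length(phosphorusIndices) < 6L)
    stop("need at least 6 phosphorus atoms, got ",
         length(phosphorusIndices))
  P <- coords[phosphorusIndices, , drop = FALSE]
  centroid <- colMeans(P)
  midplane <- as.numeric(centroid)
  if (!is.null(extracellularPoint))
    .stopIfNot3Vector(extracellularPoint, "extracellularPoint")
  if (mode == "fixed-z") {
    normal <- c(0, 0, 1)
  } else {
    normal <- if (is.null(extracellularPoint)) c(0, 0, 1)
              else .unit(extracellularPoint - centroid)
    Pc <- sweep(P, 2, centroid)
    for (it in 1:25) {
      proj <- as.vector(Pc %*% normal)
      up <- proj > 0
      if (all(up) || !any(up))
        stop("cannot split leaflets: all phosphorus atoms on one side ",
             "of the midplane")
      folded <- Pc
      folded[up, ] <- sweep(Pc[up, , drop = FALSE], 2,
                            colMeans(Pc[up, , drop = FALSE]))
      folded[!up, ] <- sweep(Pc[!up, , drop = FALSE], 2,
                             colMeans(Pc[!up, , drop = FALSE]))
      new <- svd(folded)$v[, 3]
      if (sum(new * normal) < 0) new <- -new
      delta <- acos(min(1, abs(sum(new * normal))))
      normal <- new
      if (delta < 1e-12) break
    }
  }
  ref <- if (is.null(extracellularPoint)) midplane + c(0, 0, 1)
         else extracellularPoint
  if (sum((ref - midplane) * normal) < 0) normal <- -normal
  proj <- as.vector((P - matrix(midplane, nrow(P), 3, byrow = TRUE)) %*%
                      normal)
  upper <- proj[proj > 0]; lower <- proj[proj < 0]
  if (!length(upper) || !length(lower) ||
      min(abs(mean(upper)), abs(mean(lower))) < 5)
    stop("cannot split leaflets: phosphorus atoms do not form two ",
         "separated planes (all on one side of the midplane?)")
  offsets <- c(mean(upper), mean(lower))
  if (any(abs(offsets) < 10) || any(abs(offsets) > 30))
    warning(sprintf(
      "leaflet offsets %+.1f / %+.1f A outside the physical 10-30 A range",
      offsets[1], offsets[2]))
  methods::new("MembraneGeometry", midplane = as.numeric(midplane),
               normal = as.numeric(.unit(normal)),
               leafletOffsets = offsets, frameTime = frameTime)
}

#' Signed depth of a position along the membrane normal
#'
#' Positive on the extracellular side of the midplane, negative on the
#' intracellular side, zero on the midplane. Linear along the normal.
#'
#' @param position numeric 3-vector, or an n x 3 matrix of positions.
#' @param geometry a \linkS4class{MembraneGeometry}.
#' @return signed distance(s) in Angstrom.
#' @export
signedDepth <- function(position, geometry) {
  if (is.matrix(position)) {
    d <- sweep(position, 2, geometry@midplane)
    as.vector(d %*% geometry@normal)
  } else {
    .stopIfNot3Vector(position, "position")
    sum((position - geometry@midplane) * geometry@normal)
  }
}
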