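# Accessors and show() methods for the S4 containers.

#' @rdname nFrames
#' @aliases nFrames,Trajectory-method
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname nAtoms
#' @aliases nAtoms,Trajectory-method
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname frameTimes
#' @aliases frameTimes,Trajectory-method
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname frameTimes
#' @aliases frameTimes,AngleSeries-method
#' @export
setMethod("frameTimes", "AngleSeries", function(x) x@times)

#' @rdname frameCoords
#' @aliases frameCoords,Trajectory-method
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  if (i < 1L || i > nFrames(x)) stop("frame index out of range: ", i)
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})

#' @rdname atomData
#' @aliases atomData,Trajectory-method
#' @export
setMethod("atomData", "Trajectory", function(x) x@topology)

#' @rdname boxDims
#' @aliases boxDims,Trajectory-method
#' @export
setMethod("boxDims", "Trajectory", function(x) x@box)

#' @rdname angleValues
#' @aliases angleValues,AngleSeries-method
#' @export
setMethod("angleValues", "AngleSeries", function(x) x@values)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d atoms, %d frames, dt = %g ps\n",
              nAtoms(object), nFrames(object), object@dt))
  tm <- range(object@times)
  cat(sprintf("  time range: %g .. %g ps\n", tm[1], tm[2]))
  if (nrow(object@box))
    cat(sprintf("  box (frame 1): %.1f x %.1f x %.1f A\n",
                object@box[1, 1], object@box[1, 2], object@box[1, 3]))
  else cat("  no periodic box information\n")
})

setMethod("show", "MembraneGeometry", function(object) {
  cat(sprintf(
    "MembraneGeometry @ %g ps: midplane z-ish point (%.2f, %.2f, %.2f)\n",
    object@frameTime, object@midplane[1], object@midplane[2],
    object@midplane[3]))
  cat(sprintf("  normal (%.4f, %.4f, %.4f); leaflet offsets %+.2f / %+.2f A\n",
              object@normal[1], object@normal[2], object@normal[3],
              object@leafletOffsets[1], object@leafletOffsets[2]))
})

setMethod("show", "HelixAxis", function(object) {
  cat(sprintf(
    "HelixAxis residues %g-%g: (%.4f, %.4f, %.4f), rmsFit %.2f A\n",
    object@residueRange[1], object@residueRange[2],
    object@axis[1], object@axis[2], object@axis[3], object@rmsFit))
})

setMethod("show", "AngleSeries", function(object) {
  r <- angleRange(object@kind)
  cat(sprintf("AngleSeries (%s, range [%g, %g] deg): %d frames\n",
              object@kind, r[1], r[2], length(object@values)))
  if (length(object@values))
    cat(sprintf("  linear mean %.1f deg, sd %.1f deg\n",
                mean(object@values), stats::sd(object@values)))
})

setMethod("show", "AngleSummary", function(object) {
  cat(sprintf("AngleSummary (n = %d)\n", object@n))
  cat(sprintf("  linear:   mean %.1f deg, sd %.1f deg\n",
              object@linearMean, object@linearSD))
  cat(sprintf("  circular: mean %.1f deg, sd %.1f deg, R = %.3f%s\n",
              object@circularMean, object@circularSD,
              object@resultantLength,
              if (object@weaklyConcentrated)
                " [weakly concentrated; circular mean unreliable]" else ""))
})

setMethod("show", "RDFResult", function(object) {
  cat(sprintf(
    "RDFResult '%s': %d bins to %.1f A, %d frames, %s normalisation\n",
    object@centerLabel, length(object@gValues),
    max(object@binEdges), object@nFrames, object@normalization))
  cat(sprintf("  reference density %.5f waters/A^3, total pairs %d\n",
              object@referenceDensity, as.integer(sum(object@pairCounts))))
})

setMethod("show", "RegionDefinition", function(object) {
  cat(sprintf("RegionDefinition '%s': residues %g-%g (%s atoms)\n",
              object@label, object@residueRange[1], object@residueRange[2],
              object@atomScope))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d frames x %g ps, %d-residue helix from %d\n",
    object@nFrames, object@dt, object@helixResidues,
    object@residueNumberStart))
  az <- if (object@azimuthUniform) "uniform"
        else sprintf("vonMises(%.1f, sd %.1f)", object@azimuthMean,
                     object@azimuthSD)
  cat(sprintf("  tilt vonMises(%.1f, sd %.1f) deg; azimuth %s deg\n",
              object@tiltMean, object@tiltSD, az))
  cat(sprintf(
    "  slab +/-%.1f A in %g x %g x %g A box; %d waters, %d phosphorus\n",
    object@slabHalfThickness, object@box[1], object@box[2], object@box[3],
    object@nWaters, object@nPhosphorus))
  if (!is.na(object@penetrationResidue) && object@penetrationProb > 0)
    cat(sprintf("  penetration: residue %g, p = %.2f, %d waters/event\n",
                object@penetrationResidue, object@penetrationProb,
                object@penetrationWaters))
  cat(sprintf("  IC Box1 mode: %s; seed %d\n", object@icMode, object@seed))
})
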