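# Central S4 containers. All lengths are in Angstrom, times in picoseconds,
# angles in degrees unless a slot name says otherwise.

.topologyColumns <- c("atomIndex", "atomName", "residueNumber",
                      "residueName", "segmentId", "element")

#' Trajectory: frames of coordinates bound to a topology
#'
#' An ordered set of coordinate frames together with the atom table
#' (topology) they refer to. Coordinates are stored as an
#' \code{nAtoms x 3 x nFrames} array; the optional periodic box is a
#' per-frame matrix of orthorhombic edge lengths.
#'
#' @slot topology data.frame with columns \code{atomIndex} (1-based),
#'   \code{atomName}, \code{residueNumber}, \code{residueName},
#'   \code{segmentId}, \code{element}.
#' @slot coords numeric array, \code{nAtoms x 3 x nFrames} (Angstrom).
#' @slot times numeric, strictly increasing frame times (ps).
#' @slot box numeric matrix, \code{nFrames x 3} edge lengths (Angstrom),
#'   or a 0-row matrix when absent.
#' @slot dt nominal spacing between stored frames (ps).
#'
#' @seealso \code{\link{readTrajectory}}, \code{\link{selectFrames}}
#' @export
setClass("Trajectory",
  representation(topology = "data.frame", coords = "array",
                 times = "numeric", box = "matrix", dt = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (!all(.topologyColumns %in% names(object@topology)))
    msg <- c(msg, paste("topology must have columns:",
                        paste(.topologyColumns, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
  else {
    if (d[1] != nrow(object@topology))
      msg <- c(msg, "coordinate count does not match topology atom count")
    if (d[3] != length(object@times))
      msg <- c(msg, "frame count does not match length(times)")
  }
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "frame times must be strictly increasing")
  if (any(object@times < 0))
    msg <- c(msg, "frame times must be >= 0")
  if (nrow(object@box) > 0L) {
    if (nrow(object@box) != length(object@times) || ncol(object@box) != 3L)
      msg <- c(msg, "box must be nFrames x 3 or empty")
    if (any(object@box <= 0))
      msg <- c(msg, "box edge lengths must be > 0")
  }
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' MembraneGeometry: per-frame bilayer frame of reference
#'
#' Midplane point, unit normal (oriented toward the extracellular side)
#' and signed leaflet phosphate-plane offsets estimated from lipid
#' phosphorus atoms of one frame.
#'
#' @slot midplane numeric 3-vector, a point on the midplane (Angstrom).
#' @slot normal unit 3-vector; positive direction = extracellular.
#' @slot leafletOffsets numeric 2-vector, signed distances of the two
#'   phosphate planes from the midplane (extracellular first, so the
#'   first element is positive and the second negative).
#' @slot frameTime time of the frame the geometry belongs to (ps).
#'
#' @seealso \code{\link{estimateMembraneGeometry}}, \code{\link{signedDepth}}
#' @export
setClass("MembraneGeometry",
  representation(midplane = "numeric", normal = "numeric",
                 leafletOffsets = "numeric", frameTime = "numeric"))

setValidity("MembraneGeometry", function(object) {
  msg <- character()
  if (length(object@midplane) != 3L) msg <- c(msg, "midplane must be a 3-vector")
  if (length(object@normal) != 3L) msg <- c(msg, "normal must be a 3-vector")
  else if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    msg <- c(msg, "normal must have unit length (within 1e-9)")
  if (length(object@leafletOffsets) != 2L)
    msg <- c(msg, "leafletOffsets must have length 2")
  else if (prod(sign(object@leafletOffsets)) >= 0)
    msg <- c(msg, "leafletOffsets must have opposite signs")
  if (length(msg)) msg else TRUE
})

#' HelixAxis: fitted axis of a transmembrane helix in one frame
#'
#' @slot axis unit 3-vector oriented from the first toward the last
#'   residue of the fitted range.
#' @slot centroid Calpha centroid (Angstrom).
#' @slot residueRange inclusive first/last residue numbers used.
#' @slot rmsFit RMS distance of the Calpha atoms from the fitted line
#'   (Angstrom); large values flag helix unwinding or bending.
#'
#' @seealso \code{\link{fitHelixAxis}}, \code{\link{tiltAngle}}
#' @export
setClass("HelixAxis",
  representation(axis = "numeric", centroid = "numeric",
                 residueRange = "numeric", rmsFit = "numeric"))

setValidity("HelixAxis", function(object) {
  msg <- character()
  if (length(object@axis) != 3L ||
      abs(sqrt(sum(object@axis^2)) - 1) > 1e-9)
    msg <- c(msg, "axis must be a unit 3-vector (within 1e-9)")
  if (length(object@rmsFit) != 1L || object@rmsFit < 0)
    msg <- c(msg, "rmsFit must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' AngleSeries: a time series of orientation angles
#'
#' Tilt angles live on [0, 90] degrees; azimuthal (torsion) angles on
#' (-180, 180] degrees.
#'
#' @slot times frame times (ps).
#' @slot values angles (degrees), wrapped into the range of \code{kind}.
#' @slot kind \code{"tilt"} or \code{"azimuthal"}.
#'
#' @seealso \code{\link{angleSeries}}, \code{\link{summarizeAngles}}
#' @export
setClass("AngleSeries",
  representation(times = "numeric", values = "numeric", kind = "character"))

setValidity("AngleSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (!object@kind %in% c("tilt", "azimuthal"))
    msg <- c(msg, "kind must be 'tilt' or 'azimuthal'")
  else {
    r <- angleRange(object@kind)
    bad <- object@values < r[1] - 1e-9 | object@values > r[2] + 1e-9
    if (any(bad))
      msg <- c(msg, sprintf("%d value(s) outside the %s range [%g, %g]",
                            sum(bad), object@kind, r[1], r[2]))
  }
  if (length(msg)) msg else TRUE
})

#' AngleSummary: linear and circular statistics of an angle series
#'
#' Linear statistics are the ordinary mean and standard deviation of the
#' raw values; circular statistics come from the mean resultant vector
#' (circular SD is the Mardia form \code{sqrt(-2 log R)} converted to
#' degrees). A mean resultant length below 0.2 flags a weakly
#' concentrated distribution whose circular mean is unreliable.
#'
#' @slot linearMean,linearSD degrees.
#' @slot circularMean degrees in (-180, 180].
#' @slot circularSD degrees.
#' @slot resultantLength mean resultant length in [0, 1].
#' @slot n number of observations.
#' @slot weaklyConcentrated TRUE when \code{resultantLength < 0.2}.
#'
#' @export
setClass("AngleSummary",
  representation(linearMean = "numeric", linearSD = "numeric",
                 circularMean = "numeric", circularSD = "numeric",
                 resultantLength = "numeric", n = "integer",
                 weaklyConcentrated = "logical"))

setValidity("AngleSummary", function(object) {
  msg <- character()
  if (object@resultantLength < 0 || object@resultantLength > 1 + 1e-12)
    msg <- c(msg, "resultantLength must lie in [0, 1]")
  if (object@circularSD < 0) msg <- c(msg, "circularSD must be >= 0")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(msg)) msg else TRUE
})

#' RDFResult: binned radial distribution function against water
#'
#' @slot binEdges uniform bin edges from 0 to \code{rMax} (Angstrom).
#' @slot gValues dimensionless g(r) per bin.
#' @slot pairCounts total raw pair counts per bin, summed over frames.
#' @slot referenceDensity reference water number density (waters/A^3)
#'   used for normalisation (after plateau rescaling, if requested).
#' @slot nFrames number of frames accumulated.
#' @slot centerLabel descriptor of the centre atom (e.g. "CB 505").
#' @slot normalization \code{"box"} or \code{"plateau"}.
#'
#' @seealso \code{\link{waterRDF}}, \code{\link{coordinationNumber}}
#' @export
setClass("RDFResult",
  representation(binEdges = "numeric", gValues = "numeric",
                 pairCounts = "numeric", referenceDensity = "numeric",
                 nFrames = "integer", centerLabel = "character",
                 normalization = "character"))

setValidity("RDFResult", function(object) {
  msg <- character()
  if (length(object@gValues) != length(object@binEdges) - 1L)
    msg <- c(msg, "gValues must have length(binEdges) - 1")
  if (length(object@pairCounts) != length(object@gValues))
    msg <- c(msg, "pairCounts must align with gValues")
  if (any(object@gValues < 0)) msg <- c(msg, "gValues must be >= 0")
  if (any(object@pairCounts < 0) ||
      any(abs(object@pairCounts - round(object@pairCounts)) > 1e-9))
    msg <- c(msg, "pairCounts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' RegionDefinition: a labelled residue range of interest
#'
#' @slot label unique region name, e.g. \code{"Box1"}.
#' @slot residueRange inclusive first/last residue number in the
#'   numbering scheme of the topology it is resolved against.
#' @slot atomScope \code{"heavy"} (all non-hydrogen atoms) or
#'   \code{"CA"} (Calpha only).
#'
#' @seealso \code{\link{regionDefinition}},
#'   \code{\link{regionMembraneDistance}}, \code{\link{box1Exposure}}
#' @export
setClass("RegionDefinition",
  representation(label = "character", residueRange = "numeric",
                 atomScope = "character"))

setValidity("RegionDefinition", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a non-empty string")
  if (length(object@residueRange) != 2L ||
      object@residueRange[2] < object@residueRange[1])
    msg <- c(msg, "residueRange must be an inclusive, non-empty pair")
  if (!object@atomScope %in% c("heavy", "CA"))
    msg <- c(msg, "atomScope must be 'heavy' or 'CA'")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: full parameterisation of a synthetic helix-in-bilayer
#' trajectory
#'
#' See \code{\link{syntheticSpec}} for the user constructor and the
#' meaning and defaults of every parameter.
#'
#' @slot nFrames,dt frame count and spacing (ps).
#' @slot helixResidues,residueNumberStart TM helix length (residues) and
#'   first residue number.
#' @slot tiltMean,tiltSD von Mises tilt distribution (degrees).
#' @slot azimuthMean,azimuthSD von Mises azimuth distribution (degrees).
#' @slot azimuthUniform when TRUE the azimuth is uniform on (-180, 180].
#' @slot slabHalfThickness distance of each phosphate pseudo-plane from
#'   the midplane (Angstrom).
#' @slot box orthorhombic edge lengths (Angstrom).
#' @slot nWaters,nPhosphorus particle counts.
#' @slot penetrationResidue residue number near which rare
#'   water-penetration events occur (NA disables).
#' @slot penetrationProb per-frame event probability in [0, 1].
#' @slot penetrationWaters waters moved to the residue per event.
#' @slot icMode Box1 placement: \code{"open"} (solvent-exposed) or
#'   \code{"packed"} (buried at the membrane surface).
#' @slot seed RNG seed; identical specs generate identical systems.
#'
#' @export
setClass("SyntheticSpec",
  representation(nFrames = "integer", dt = "numeric",
                 helixResidues = "integer", residueNumberStart = "integer",
                 tiltMean = "numeric", tiltSD = "numeric",
                 azimuthMean = "numeric", azimuthSD = "numeric",
                 azimuthUniform = "logical",
                 slabHalfThickness = "numeric", box = "numeric",
                 nWaters = "integer", nPhosphorus = "integer",
                 penetrationResidue = "numeric", penetrationProb = "numeric",
                 penetrationWaters = "integer",
                 icMode = "character", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@helixResidues < 4L) msg <- c(msg, "helixResidues must be >= 4")
  if (!object@azimuthUniform && object@azimuthSD < 0)
    msg <- c(msg, "azimuthSD must be >= 0")
  if (object@tiltSD < 0) msg <- c(msg, "tiltSD must be >= 0")
  if (length(object@box) != 3L || any(object@box <= 0))
    msg <- c(msg, "box must be 3 positive edge lengths")
  if (object@slabHalfThickness <= 0)
    msg <- c(msg, "slabHalfThickness must be > 0")
  if (object@nWaters < 0L) msg <- c(msg, "nWaters must be >= 0")
  if (object@nPhosphorus < 6L) msg <- c(msg, "nPhosphorus must be >= 6")
  if (object@penetrationProb < 0 || object@penetrationProb > 1)
    msg <- c(msg, "penetrationProb must be in [0, 1]")
  if (!object@icMode %in% c("open", "packed"))
    msg <- c(msg, "icMode must be 'open' or 'packed'")
  if (length(msg)) msg else TRUE
})
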