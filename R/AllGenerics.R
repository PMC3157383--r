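#' @include AllClasses.R
NULL

#' Number of frames in a trajectory-like object
#'
#' @param x a \linkS4class{Trajectory} (or other object with frames).
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms bound to a topology
#'
#' @param x a \linkS4class{Trajectory}.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Frame times in picoseconds
#'
#' @param x a \linkS4class{Trajectory} or \linkS4class{AngleSeries}.
#' @return numeric vector of times (ps).
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Coordinates of one frame
#'
#' @param x a \linkS4class{Trajectory}.
#' @param i frame index (1-based).
#' @return numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' Atom table of a trajectory topology
#'
#' @param x a \linkS4class{Trajectory}.
#' @return data.frame of atom records (see \code{\link{readTopology}}).
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Periodic box edge lengths
#'
#' @param x a \linkS4class{Trajectory}.
#' @return numeric matrix (frames x 3) of orthorhombic edge lengths in
#'   Angstrom, or a 0-row matrix when no box information is available.
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' Angle values of a series
#'
#' @param x an \linkS4class{AngleSeries}.
#' @return numeric vector of angles in degrees.
#' @export
setGeneric("angleValues", function(x) standardGeneric("angleValues"))
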