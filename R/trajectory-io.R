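# Topology/trajectory reading, atom selection and frame windowing.
# PDB parsing and DCD reading go through bio3d; the DCD writer
# (CHARMM/NAMD flavour) lives in dcd-write.R.

#' Construct a Trajectory from in-memory pieces
#'
#' Low-level constructor used by the file readers and the synthetic
#' generator; validity checks (dimension agreement, increasing times,
#' positive box edges) are enforced.
#'
#' @param topology atom table as returned by \code{\link{readTopology}}.
#' @param coords numeric array \code{nAtoms x 3 x nFrames} (Angstrom).
#' @param times frame times in ps; defaults to \code{0, dt, 2 dt, ...}.
#' @param box per-frame orthorhombic edge lengths: a 3-vector (recycled),
#'   an \code{nFrames x 3} matrix, or NULL for no box.
#' @param dt nominal frame spacing (ps).
#' @return a \linkS4class{Trajectory}.
#' @export
newTrajectory <- function(topology, coords, times = NULL, box = NULL,
                          dt = 10) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (is.null(box)) box <- matrix(numeric(), 0L, 3L)
  else if (is.vector(box) && length(box) == 3L)
    box <- matrix(box, nf, 3L, byrow = TRUE)
  methods::new("Trajectory", topology = topology, coords = coords,
               times = as.numeric(times), box = box, dt = dt)
}

#' Read a PDB topology
#'
#' Parses every ATOM/HETATM record into one atom row. Residue numbering
#' is preserved verbatim from the file. Atom indices are 1-based.
#'
#' @param path PDB file.
#' @return data.frame with columns \code{atomIndex}, \code{atomName},
#'   \code{residueNumber}, \code{residueName}, \code{segmentId},
#'   \code{element}, plus attribute \code{"box"} (CRYST1 edge lengths)
#'   when the file carries one.
#' @export
readTopology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("unparseable PDB '", path, "': ",
                         conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms in ", path)
  topo <- data.frame(
    atomIndex = seq_len(nrow(a)),
    atomName = as.character(a$elety),
    residueNumber = as.integer(a$resno),
    residueName = as.character(a$resid),
    segmentId = ifelse(is.na(a$segid) | a$segid == "",
                       as.character(a$chain), as.character(a$segid)),
    element = as.character(a$elesy),
    stringsAsFactors = FALSE)
  topo$segmentId[is.na(topo$segmentId)] <- ""
  topo$element[is.na(topo$element)] <- ""
  cr <- .readCryst1(path)
  if (!is.null(cr)) attr(topo, "box") <- cr
  topo
}

# CRYST1 a b c (orthorhombic assumed when angles are 90).
.readCryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 500L), value = TRUE)
  if (!length(ln)) return(NULL)
  v <- suppressWarnings(as.numeric(c(substr(ln[1], 7, 15),
                                     substr(ln[1], 16, 24),
                                     substr(ln[1], 25, 33))))
  if (any(is.na(v)) || any(v <= 0)) NULL else v
}

#' Read a coordinate trajectory bound to a topology
#'
#' Supports CHARMM/NAMD DCD (via \code{bio3d::read.dcd}) and multi-model
#' PDB. Frame times are assigned as \code{time0 + frameIndex * dt}
#' (frameIndex from 0). The periodic box is taken per frame from the DCD
#' unit-cell records when present, else from the topology's CRYST1.
#'
#' @param topology atom table from \code{\link{readTopology}}.
#' @param path DCD or multi-model PDB file.
#' @param dt nominal frame spacing (ps).
#' @param time0 time of the first stored frame (ps).
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(topology, path, dt = 10, time0 = 0) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  isDCD <- grepl("\\.dcd$", path, ignore.case = TRUE) ||
    .looksLikeDCD(path)
  if (isDCD) {
    xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
    box <- .readDCDCell(path)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
    box <- NULL
  }
  na <- ncol(xyz) / 3L
  if (na != nrow(topology))
    stop(sprintf("atom-count mismatch: trajectory has %d atoms, topology %d",
                 na, nrow(topology)))
  nf <- nrow(xyz)
  coords <- aperm(array(t(xyz), c(3L, na, nf)), c(2L, 1L, 3L))
  if (is.null(box)) {
    cr <- attr(topology, "box")
    box <- if (is.null(cr)) NULL else cr
  }
  newTrajectory(topology, coords,
                times = time0 + (seq_len(nf) - 1) * dt, box = box, dt = dt)
}

.looksLikeDCD <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 8L)
  length(hdr) == 8L && rawToChar(hdr[5:8]) == "CORD"
}

# Per-frame orthorhombic edges from the DCD unit-cell records, or NULL.
.readDCDCell <- function(path) {
  if (!.dcdHasCell(path)) return(NULL)
  cell <- suppressWarnings(bio3d::read.dcd(path, cell = TRUE,
                                           verbose = FALSE))
  cell[, 1:3, drop = FALSE]
}

.dcdHasCell <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 8L)                       # marker + CORD
  icntrl <- readBin(con, "integer", 20L, size = 4L)
  icntrl[11] == 1L
}

#' Select atoms by name, residue range and segment
#'
#' Conjunction semantics: every non-NULL criterion must hold. An empty
#' selection is a valid result, not an error.
#'
#' @param topology atom table from \code{\link{readTopology}}.
#' @param atomNames character vector of atom names (e.g. \code{"CA"}).
#' @param residues integer vector (typically a range) of residue numbers.
#' @param segment segment identifier(s).
#' @param residueNames residue name(s) (e.g. water residue dialects).
#' @return ascending integer vector of 1-based atom indices.
#' @export
selectAtoms <- function(topology, atomNames = NULL, residues = NULL,
                        segment = NULL, residueNames = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(atomNames)) keep <- keep & topology$atomName %in% atomNames
  if (!is.null(residues)) keep <- keep & topology$residueNumber %in% residues
  if (!is.null(segment)) keep <- keep & topology$segmentId %in% segment
  if (!is.null(residueNames))
    keep <- keep & topology$residueName %in% residueNames
  sort(topology$atomIndex[keep])
}

#' Select water oxygen atoms
#'
#' Water naming varies across PDB writers; both the oxygen atom names
#' and the water residue names are configurable sets.
#'
#' @param topology atom table.
#' @param oxygenNames accepted oxygen atom names.
#' @param waterResidues accepted water residue names.
#' @return ascending atom indices of water oxygens.
#' @export
selectWaterOxygens <- function(topology,
                               oxygenNames = c("OH2", "OW", "O"),
                               waterResidues = c("TIP3", "HOH", "WAT",
                                                 "SOL")) {
  selectAtoms(topology, atomNames = oxygenNames,
              residueNames = waterResidues)
}

#' Slice a trajectory by time window and stride
#'
#' Keeps frames with time t in the half-open window
#' \code{windowStart < t <= windowEnd} whose offset from
#' \code{windowEnd} is a multiple of \code{stride}. Anchoring the stride
#' grid at the window end makes a "last 100 ns at 10 ps" window of a
#' 10-ps trajectory contain exactly 10,000 frames.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param windowStart,windowEnd window bounds in ps (exclusive start,
#'   inclusive end).
#' @param stride sampling interval in ps; must be a positive integer
#'   multiple of the trajectory's nominal dt.
#' @return a \linkS4class{Trajectory} containing the selected frames.
#' @seealso \code{\link{lastWindow}}
#' @export
selectFrames <- function(trajectory, windowStart, windowEnd, stride) {
  if (windowStart >= windowEnd)
    stop("windowStart must be < windowEnd")
  if (stride <= 0) stop("stride must be > 0")
  dt <- trajectory@dt
  if (abs(stride / dt - round(stride / dt)) > 1e-9)
    stop(sprintf("stride %g ps is not a multiple of the stored dt %g ps",
                 stride, dt))
  tms <- trajectory@times
  eps <- dt * 1e-6
  if (windowEnd > max(tms) + eps || windowStart < min(tms) - dt - eps)
    stop(sprintf(
      "window (%g, %g] outside trajectory time range [%g, %g] ps",
      windowStart, windowEnd, min(tms), max(tms)))
  off <- (windowEnd - tms) / stride
  keep <- tms > windowStart + eps & tms <= windowEnd + eps &
    abs(off - round(off)) < 1e-6
  idx <- which(keep)
  if (!length(idx)) stop("no frames in the requested window")
  newTrajectory(trajectory@topology,
                trajectory@coords[, , idx, drop = FALSE],
                times = tms[idx],
                box = if (nrow(trajectory@box))
                        trajectory@box[idx, , drop = FALSE] else NULL,
                dt = trajectory@dt)
}

#' Window bounds for the last N nanoseconds of a trajectory
#'
#' Anchored at the final frame time, so the window
#' \code{(tEnd - ns * 1000, tEnd]} at stride s contains exactly
#' \code{ns * 1000 / s} frames of an s-commensurate trajectory.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param ns window length in nanoseconds.
#' @return numeric \code{c(start, end)} in ps.
#' @export
lastWindow <- function(trajectory, ns) {
  tEnd <- max(trajectory@times)
  c(tEnd - ns * 1000, tEnd)
}

#' Write a trajectory's topology as PDB
#'
#' One ATOM record per topology row, coordinates from the requested
#' frame, plus a CRYST1 record when the trajectory has a box.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param path output PDB file.
#' @param frame frame index whose coordinates to write.
#' @return \code{path}, invisibly.
#' @export
writeTopologyPDB <- function(trajectory, path, frame = 1L) {
  topo <- trajectory@topology
  xyz <- as.vector(t(frameCoords(trajectory, frame)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = topo$residueNumber, resid = topo$residueName,
                   eleno = topo$atomIndex, elety = topo$atomName,
                   segid = topo$segmentId, elesy = topo$element,
                   print.segid = TRUE)
  if (nrow(trajectory@box)) {
    b <- trajectory@box[frame, ]
    cryst <- sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      b[1], b[2], b[3], 90, 90, 90)
    lns <- readLines(path)
    writeLines(c(cryst, lns), path)
  }
  invisible(path)
}
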