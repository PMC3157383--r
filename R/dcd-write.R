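# Minimal CHARMM/NAMD-flavour DCD writer (32-bit record markers,
# version-24 header, single-precision coordinates, unit-cell records
# with cosine angles). No installed R package writes DCD; reading back
# is done with bio3d::read.dcd, which serves as the independent check.

#' Write a trajectory as a CHARMM/NAMD DCD file
#'
#' Coordinates are stored in single precision (round-trip accurate to
#' about 1e-3 Angstrom at typical magnitudes). When the trajectory
#' carries a box, per-frame unit-cell records are written (orthorhombic,
#' angle cosines = 0).
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readTrajectory}}
#' @export
writeTrajectoryDCD <- function(trajectory, path) {
  coords <- trajectory@coords
  box <- trajectory@box
  nf <- dim(coords)[3]; na <- dim(coords)[1]
  hasCell <- nrow(box) > 0L
  con <- file(path, "wb"); on.exit(close(con))
  icntrl <- integer(20L)
  icntrl[1] <- nf                       # frames in file
  icntrl[2] <- 0L                       # first step
  icntrl[3] <- 1L                       # steps between frames
  icntrl[4] <- nf
  icntrl[11] <- as.integer(hasCell)
  icntrl[20] <- 24L                     # CHARMM version tag
  writeBin(84L, con, size = 4L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  writeBin(icntrl[1:9], con, size = 4L)
  writeBin(as.numeric(trajectory@dt), con, size = 4L)  # delta (float)
  writeBin(icntrl[11:20], con, size = 4L)
  writeBin(84L, con, size = 4L)
  title <- sprintf("%-80s", "Synthetic helix-in-bilayer trajectory")
  writeBin(84L, con, size = 4L)
  writeBin(1L, con, size = 4L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  writeBin(84L, con, size = 4L)
  writeBin(4L, con, size = 4L)
  writeBin(as.integer(na), con, size = 4L)
  writeBin(4L, con, size = 4L)
  for (f in seq_len(nf)) {
    if (hasCell) {
      b <- box[f, ]
      cell <- c(b[1], 0, b[2], 0, 0, b[3])  # a, cos(g), b, cos(b), cos(a), c
      writeBin(48L, con, size = 4L)
      writeBin(as.numeric(cell), con, size = 8L)
      writeBin(48L, con, size = 4L)
    }
    for (d in 1:3) {
      writeBin(as.integer(4L * na), con, size = 4L)
      writeBin(as.numeric(coords[, d, f]), con, size = 4L)
      writeBin(as.integer(4L * na), con, size = 4L)
    }
  }
  invisible(path)
}
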