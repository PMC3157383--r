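# Helix axis fitting, tilt and azimuthal (torsion) angles, circular
# summaries and normalised angle histograms.

#' Fit the axis of a transmembrane helix
#'
#' Two estimators are available. \code{"curvature"} (default) takes the
#' axis as the null direction (smallest right-singular vector) of the
#' second-difference vectors \code{p[i+1] - 2 p[i] + p[i-1]}, which are
#' exactly perpendicular to the axis of an ideal helix for any number of
#' turns; it is therefore bias-free on regular helices.
#' \code{"svd"} takes the first right-singular vector of the
#' mean-centred Calpha coordinates; it is more robust to irregular
#' geometry but carries a small bias (a fraction of a degree) when the
#' helix covers a non-integer number of turns.
#'
#' The axis sign always points from the first toward the last residue
#' of the selection. \code{rmsFit} is the RMS distance of the Calpha
#' atoms from the fitted line; values above 3 Angstrom trigger a
#' warning, since a poorly helical segment makes the axis ill-defined.
#'
#' @param coords frame coordinate matrix (\code{\link{frameCoords}}).
#' @param caIndices atom indices of the Calpha atoms, in residue order
#'   (>= 4).
#' @param method \code{"curvature"} or \code{"svd"}.
#' @param residueRange optional first/last residue numbers, recorded in
#'   the result.
#' @return a \linkS4class{HelixAxis}.
#' @export
fitHelixAxis <- function(coords, caIndices,
                         method = c("curvature", "svd"),
                         residueRange = c(NA_real_, NA_real_)) {
  method <- match.arg(method)
  if (length(caIndices) < 4L)
    stop("need at least 4 Calpha atoms, got ", length(caIndices))
  ca <- coords[caIndices, , drop = FALSE]
  centroid <- colMeans(ca)
  cc <- sweep(ca, 2, centroid)
  if (max(abs(cc)) < 1e-9)
    stop("degenerate Calpha coordinates (all coincident)")
  n <- nrow(ca)
  chord <- ca[n, ] - ca[1, ]
  if (method == "curvature") {
    u <- ca[3:n, , drop = FALSE] - 2 * ca[2:(n - 1), , drop = FALSE] +
      ca[1:(n - 2), , drop = FALSE]
    nz <- sqrt(rowSums(u^2)) > 1e-9
    axis <- if (sum(nz) >= 2L) svd(u[nz, , drop = FALSE])$v[, 3]
            else .unit(chord)   # collinear points have no curvature
  } else {
    axis <- svd(cc)$v[, 1]
  }
  if (sum(axis * chord) < 0) axis <- -axis
  proj <- cc %*% axis
  rmsFit <- sqrt(mean(rowSums((cc - proj %*% t(axis))^2)))
  if (rmsFit > 3)
    warning(sprintf(
      "rmsFit %.2f A > 3 A: segment poorly helical, axis may be unstable",
      rmsFit))
  methods::new("HelixAxis", axis = as.numeric(.unit(axis)),
               centroid = as.numeric(centroid),
               residueRange = as.numeric(residueRange), rmsFit = rmsFit)
}

#' Tilt angle of a helix axis against the membrane normal
#'
#' \code{acos(|axis . normal|)} in degrees, folded into [0, 90] so the
#' result does not depend on either sign convention.
#'
#' @param axis a \linkS4class{HelixAxis}.
#' @param geometry a \linkS4class{MembraneGeometry}.
#' @return tilt in degrees, [0, 90].
#' @export
tiltAngle <- function(axis, geometry) {
  d <- abs(sum(axis@axis * geometry@normal))
  .deg(acos(min(1, d)))
}

#' Torsion (dihedral) angle over four points
#'
#' Standard IUPAC convention: the signed angle between the plane of
#' (p1, p2, p3) and the plane of (p2, p3, p4), with the sign given by
#' the right-hand rule about p2 -> p3. Cis = 0 degrees, trans = 180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return degrees in (-180, 180].
#' @export
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
      sqrt(sum(b3^2)) < 1e-9)
    stop("undefined torsion: consecutive points coincide")
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("undefined torsion: collinear triple of points")
  m <- .cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- .deg(atan2(sum(m * n2), sum(n1 * n2)))
  wrapAngle(ang)
}

#' Per-frame orientation angle series of a trajectory
#'
#' For \code{observable = "tilt"}, each frame's membrane geometry is
#' estimated from the phosphorus atoms, the helix axis is fitted to the
#' Calpha selection, and the tilt angle is recorded. For
#' \code{observable = "azimuthal"}, the torsion over the four configured
#' Calpha atoms is recorded. Apply \code{\link{selectFrames}} first to
#' impose the analysis window and stride.
#'
#' @param trajectory a (windowed/strided) \linkS4class{Trajectory}.
#' @param observable \code{"tilt"} or \code{"azimuthal"}.
#' @param caIndices Calpha indices of the TM helix (tilt).
#' @param quadIndices the four Calpha indices defining the azimuthal
#'   torsion (azimuthal).
#' @param phosphorusIndices lipid phosphorus indices (tilt).
#' @param geometryMode passed to \code{\link{estimateMembraneGeometry}}.
#' @param axisMethod passed to \code{\link{fitHelixAxis}}.
#' @return an \linkS4class{AngleSeries}.
#' @export
angleSeries <- function(trajectory,
                        observable = c("tilt", "azimuthal"),
                        caIndices = NULL, quadIndices = NULL,
                        phosphorusIndices = NULL,
                        geometryMode = "fixed-z",
                        axisMethod = "curvature") {
  observable <- match.arg(observable)
  nf <- nFrames(trajectory)
  vals <- numeric(nf)
  if (observable == "tilt") {
    if (is.null(caIndices) || is.null(phosphorusIndices))
      stop("tilt series needs caIndices and phosphorusIndices")
    for (f in seq_len(nf)) {
      co <- frameCoords(trajectory, f)
      vals[f] <- tryCatch({
        geo <- estimateMembraneGeometry(
          co, phosphorusIndices, mode = geometryMode,
          frameTime = trajectory@times[f])
        ax <- fitHelixAxis(co, caIndices, method = axisMethod)
        tiltAngle(ax, geo)
      }, error = function(e)
        stop(sprintf("frame at %g ps: %s", trajectory@times[f],
                     conditionMessage(e)), call. = FALSE))
    }
  } else {
    if (is.null(quadIndices) || length(quadIndices) != 4L)
      stop("azimuthal series needs exactly 4 quadIndices")
    for (f in seq_len(nf)) {
      co <- frameCoords(trajectory, f)
      vals[f] <- tryCatch(
        torsionAngle(co[quadIndices[1], ], co[quadIndices[2], ],
                     co[quadIndices[3], ], co[quadIndices[4], ]),
        error = function(e)
          stop(sprintf("frame at %g ps: %s", trajectory@times[f],
                       conditionMessage(e)), call. = FALSE))
    }
  }
  methods::new("AngleSeries", times = trajectory@times, values = vals,
               kind = observable)
}

#' Linear and circular summary of an angle series
#'
#' The linear mean/SD are computed on the raw values (appropriate for
#' the bounded tilt range); the circular mean, mean resultant length
#' and Mardia circular SD come from \code{\link{circularStats}}
#' (appropriate for azimuthal angles, which wrap). Both are always
#' reported, along with a weak-concentration flag
#' (\code{resultantLength < 0.2}), under which the circular mean is
#' unreliable.
#'
#' @param series an \linkS4class{AngleSeries}.
#' @return an \linkS4class{AngleSummary}.
#' @export
summarizeAngles <- function(series) {
  v <- series@values
  if (!length(v)) stop("empty angle series")
  cs <- circularStats(v)
  methods::new("AngleSummary",
               linearMean = mean(v),
               linearSD = if (length(v) > 1L) stats::sd(v) else 0,
               circularMean = cs$mean,
               circularSD = cs$sd,
               resultantLength = cs$R,
               n = length(v),
               weaklyConcentrated = cs$R < 0.2)
}

#' Normalised histogram of an angle series
#'
#' Bins cover the observable's full range ([0, 90] for tilt,
#' (-180, 180] for azimuthal) including empty bins; densities integrate
#' to 1 (sum(density) * binWidth = 1).
#'
#' @param series an \linkS4class{AngleSeries}.
#' @param binWidth bin width in degrees; must divide the range.
#' @return data.frame with \code{mid} (bin centre, degrees),
#'   \code{count} and \code{density} (1/degree).
#' @export
angleHistogram <- function(series, binWidth = 10) {
  r <- angleRange(series@kind)
  span <- r[2] - r[1]
  if (abs(span / binWidth - round(span / binWidth)) > 1e-9)
    stop(sprintf("binWidth %g does not divide the %g-degree range",
                 binWidth, span))
  nb <- round(span / binWidth)
  edges <- r[1] + binWidth * (0:nb)
  v <- series@values
  # right-closed bins match the (-180, 180] wrap; clamp the tilt lower
  # edge so an exact 0 lands in the first bin
  bin <- pmax(1L, ceiling((v - r[1]) / binWidth - 1e-12))
  bin <- pmin(bin, nb)
  count <- tabulate(bin, nbins = nb)
  data.frame(mid = edges[-1] - binWidth / 2,
             count = count,
             density = count / (length(v) * binWidth))
}
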