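# Small shared geometry/angle helpers (internal).

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

# Valid range of an angle observable, degrees.
angleRange <- function(kind) {
  switch(kind,
         tilt = c(0, 90),
         azimuthal = c(-180, 180),
         stop("unknown angle kind: ", kind))
}

# Wrap degrees into (-180, 180].
wrapAngle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrices (right-handed, active), angle in degrees.
.rotX <- function(deg) {
  t <- .rad(deg); c0 <- cos(t); s0 <- sin(t)
  rbind(c(1, 0, 0), c(0, c0, -s0), c(0, s0, c0))
}
.rotY <- function(deg) {
  t <- .rad(deg); c0 <- cos(t); s0 <- sin(t)
  rbind(c(c0, 0, s0), c(0, 1, 0), c(-s0, 0, c0))
}
.rotZ <- function(deg) {
  t <- .rad(deg); c0 <- cos(t); s0 <- sin(t)
  rbind(c(c0, -s0, 0), c(s0, c0, 0), c(0, 0, 1))
}

.stopIfNot3Vector <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop(what, " must be a finite numeric 3-vector")
  invisible(x)
}
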