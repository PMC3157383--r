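# Circular statistics and von Mises sampling. Angles are degrees at the
# interface, radians internally.

#' Circular mean, resultant length and circular SD of angles
#'
#' Computes the mean resultant vector of a sample of angles. The
#' circular mean is its direction; the mean resultant length R measures
#' concentration (1 = all angles identical, 0 = perfectly dispersed);
#' the circular standard deviation is \code{sqrt(-2 log R)} in degrees.
#'
#' @param deg numeric vector of angles in degrees.
#' @return list with \code{mean} (degrees in (-180, 180]),
#'   \code{R} (resultant length) and \code{sd} (degrees).
#' @examples
#' circularStats(c(350, 10))$mean  # 0, where the linear mean is 180
#' @export
circularStats <- function(deg) {
  if (!length(deg)) stop("need at least one angle")
  th <- .rad(deg)
  s <- mean(sin(th)); c0 <- mean(cos(th))
  R <- min(1, sqrt(s^2 + c0^2))
  m <- if (R < .Machine$double.eps) 0 else .deg(atan2(s, c0))
  sdv <- if (R <= 0) Inf else .deg(sqrt(-2 * log(R)))
  list(mean = wrapAngle(m), R = R, sd = sdv)
}

#' von Mises concentration for a requested circular SD
#'
#' Solves the concentration parameter kappa such that a von Mises
#' distribution has mean resultant length \code{exp(-sd^2/2)} (the value
#' whose Mardia circular SD equals \code{sdDeg}). \code{sdDeg = 0} maps
#' to \code{Inf} (a point mass); very large SDs map to 0 (uniform).
#'
#' @param sdDeg requested circular standard deviation in degrees.
#' @return kappa (dimensionless concentration).
#' @export
vonMisesConcentration <- function(sdDeg) {
  if (sdDeg < 0) stop("sdDeg must be >= 0")
  if (sdDeg == 0) return(Inf)
  targetR <- exp(-.rad(sdDeg)^2 / 2)
  if (targetR < 1e-8) return(0)
  # I1/I0, switching to the large-kappa expansion where besselI
  # overflows its argument range
  A <- function(k)
    if (k > 5e3) 1 - 1 / (2 * k) - 1 / (8 * k^2) - 1 / (8 * k^3)
    else besselI(k, 1, expon.scaled = TRUE) /
         besselI(k, 0, expon.scaled = TRUE)
  upper <- 1e12
  if (targetR >= A(upper)) return(1 / (2 * (1 - targetR)))
  stats::uniroot(function(k) A(k) - targetR,
                 lower = 1e-8, upper = upper, tol = 1e-12)$root
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. \code{kappa = 0} gives the uniform
#' circular distribution; \code{kappa = Inf} a point mass at \code{mu}.
#' Uses the current RNG state (set a seed for reproducibility).
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0, may be Inf).
#' @return angles in degrees, wrapped into (-180, 180].
#' @export
rVonMises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (!is.finite(kappa)) return(rep(wrapAngle(mu), n))
  if (kappa == 0) return(wrapAngle(stats::runif(n, -180, 180)))
  muR <- .rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      out[i] <- muR + sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  wrapAngle(.deg(out))
}
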