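#' Axial von Mises statistics for fiber and cell orientations
#'
#' Fiber orientations are axial data: an angle and its 180-degree rotation
#' are the same fiber, so angles live in (-90, 90] degrees with 0 = the
#' vessel's axial direction.  The standard treatment doubles the angles to
#' map axial data onto the full circle, fits a von Mises distribution
#' there, and halves the mean direction back.  The concentration parameter
#' kappa is the inverse-width of the distribution: low kappa means broadly
#' distributed fibers, high kappa tight alignment.
#'
#' @name circular-stats
NULL

# ratio A1(kappa) = I1(kappa)/I0(kappa), numerically stable at large kappa
A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# invert A1(kappa) = r for r in [0, 1): series initialization
# (Banerjee et al. approximation) refined by safeguarded Newton steps
solve_kappa <- function(r, cap = 1e3) {
  if (r <= 0) return(0)
  if (r >= 1 - 1e-12) return(cap)
  k <- r * (2 - r^2) / (1 - r^2)
  k <- min(max(k, 1e-8), cap)
  # A1'(k) = 1 - A1/k - A1^2
  for (i in 1:50) {
    a <- A1(k)
    da <- 1 - a / k - a^2
    step <- (a - r) / da
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (k_new > cap) return(cap)
    if (abs(k_new - k) < 1e-12 * (1 + k)) { k <- k_new; break }
    k <- k_new
  }
  min(k, cap)
}

#' Maximum-likelihood axial von Mises fit
#'
#' Doubles the angles, computes the (weighted) mean resultant length
#' \eqn{\bar R} and circular mean on the doubled circle, then solves the
#' ML equation \eqn{I_1(\kappa)/I_0(\kappa) = \bar R} for the
#' concentration parameter by Newton iteration from the standard series
#' initialization.  kappa is capped at 1000; a cap hit is flagged.
#'
#' @param angles_deg orientation samples in degrees, interpreted modulo
#'   180; any real values accepted.
#' @param weights optional nonnegative weights (e.g. structure-tensor
#'   coherence); total weight must be positive.
#' @return list with \code{theta_bar_deg} (mean orientation in (-90, 90]),
#'   \code{kappa}, \code{R_bar} (mean resultant length of the doubled
#'   angles), \code{n} (total weight) and \code{capped}.
#' @export
fit_von_mises_axial <- function(angles_deg, weights = NULL) {
  stopifnot(length(angles_deg) > 0)
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  stopifnot(length(weights) == length(angles_deg), all(weights >= 0))
  W <- sum(weights)
  if (W <= 0) stop("total weight must be positive")
  phi <- 2 * angles_deg * pi / 180
  C <- sum(weights * cos(phi)) / W
  S <- sum(weights * sin(phi)) / W
  R_bar <- sqrt(C^2 + S^2)
  theta <- atan2(S, C) / 2 * 180 / pi        # in (-90, 90]
  if (theta <= -90) theta <- theta + 180
  kappa <- solve_kappa(R_bar)
  list(theta_bar_deg = theta, kappa = kappa, R_bar = R_bar, n = W,
       capped = R_bar >= 1 - 1e-12)
}

# von Mises sampler on the full circle (Best & Fisher 1979
# acceptance-rejection); mean direction mu (radians), concentration kappa
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  out
}

#' Draw axial von Mises orientation samples
#'
#' Samples from a von Mises distribution with mean direction
#' \eqn{2\bar\theta} and concentration kappa on the doubled circle, halves
#' the angles and wraps them into (-90, 90].  kappa = 0 gives the uniform
#' (isotropic) distribution.
#'
#' @param n number of samples.
#' @param theta_bar_deg mean orientation in degrees.
#' @param kappa concentration parameter, \eqn{\ge 0}.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return numeric vector of angles in (-90, 90] degrees.
#' @export
sample_axial_von_mises <- function(n, theta_bar_deg, kappa, seed = NULL) {
  stopifnot(n > 0, kappa >= 0)
  phi <- with_seed(seed, rvonmises(n, 2 * theta_bar_deg * pi / 180, kappa))
  ang <- (phi / 2) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  ang[ang == -90] <- 90
  ang
}
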