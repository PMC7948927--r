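#' Circular mean of angles
#'
#' Direction of the resultant vector, `atan2(mean sin, mean cos)`, in
#' degrees in (-180, 180]. When the resultant length is (numerically)
#' zero the mean direction is undefined and `NA` is returned with a
#' warning.
#'
#' @param x angles in degrees (`NA` dropped).
#' @param tol resultant-length threshold below which the mean is
#'   flagged undefined.
#' @return Mean direction in degrees, or `NA`.
#' @export
circular_mean <- function(x, tol = 1e-8) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty angle series")
  r <- x * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  if (sqrt(s^2 + c^2) < tol) {
    warning("resultant length ~ 0: circular mean undefined")
    return(NA_real_)
  }
  wrap_angle(atan2(s, c) * 180 / pi)
}

#' Minimal signed circular difference a - b
#'
#' @param a,b angles in degrees (vectorized).
#' @return Signed difference in degrees in (-180, 180].
#' @export
circular_diff <- function(a, b) wrap_angle(a - b)

#' Sample from the von Mises distribution (degrees)
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` falls back to the
#' circular uniform. Uses the current RNG stream.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0).
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-10) return(wrap_angle(runif(n, -180, 180)))
  mu_r <- mu * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3 - 0.5)[ok] * acos(f[ok])
    k <- length(theta)
    if (k > 0L) {
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle((mu_r + out) * 180 / pi)
}
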