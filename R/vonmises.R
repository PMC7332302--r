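#' Wrap angles to (-pi, pi]
#' @param x Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampling of the circular normal distribution
#' with mean direction \code{mu} and concentration \code{kappa}.
#' \code{kappa = 0} gives the uniform distribution on the circle. The
#' mean resultant length of the distribution is the Bessel-function
#' ratio I1(kappa)/I0(kappa).
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration parameter, >= 0.
#' @return \code{n} angles in (-pi, pi].
#' @references Best, D.J. and Fisher, N.I. (1979). Efficient simulation
#'   of the von Mises distribution. Applied Statistics 28, 152-157.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0 || !is.finite(kappa)) stop("kappa must be finite and >= 0",
                                           call. = FALSE)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(n - got, 16L)          # batch rejection; acceptance rate > 65%
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- f[ok]
    s <- sign(u3[ok] - 0.5)
    take <- min(length(acc), n - got)
    if (take > 0) {
      out[(got + 1):(got + take)] <- s[seq_len(take)] * acos(acc[seq_len(take)])
      got <- got + take
    }
  }
  wrap_angle(mu + out)
}
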