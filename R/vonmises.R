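#' Draw von Mises distributed angles
#'
#' Samples from the von Mises distribution with mean direction `mu` and
#' concentration `kappa`, using the Best-Fisher (1979) wrapped-Cauchy
#' envelope rejection scheme. `kappa = 0` reduces to the uniform
#' distribution on the circle. Draws consume the global R random stream,
#' so results are reproducible under `set.seed()`.
#'
#' @param n number of draws.
#' @param mu mean direction in radians (scalar or length `n`).
#' @param kappa concentration parameter, >= 0.
#' @return Numeric vector of `n` angles in radians, reduced to
#'   (-pi, pi] around `mu`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0, is.finite(kappa))
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9) return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    m <- length(need)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    accept <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    out[need[accept]] <- theta[accept]
    need <- need[!accept]
  }
  wrap_angle(out + mu)
}

#' Reduce angles to (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return Angles wrapped into the interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor(theta / (2 * pi) + 0.5)
  ## floor(x + 0.5) maps the lower boundary -pi to itself; fold to +pi
  w[w <= -pi] <- pi
  w
}
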