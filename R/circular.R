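#' Circular summary and uniformity tests
#'
#' Directional statistics used throughout the trajectory toolkit. A
#' `circular_result` bundles the sample of angles with its mean
#' direction, mean resultant length \eqn{\bar R}, circular dispersion
#' (circular standard deviation \eqn{\sqrt{-2\ln\bar R}}), and a
#' uniformity test: Rayleigh when no direction is expected, V test when
#' the alternative is concentration around a known direction.
#'
#' @name circular_result
#' @param angles numeric vector of angles in radians.
#' @param mean_direction,mean_resultant_length,circular_dispersion,statistic,p_value,test
#'   components as computed by [rayleigh_test()] or [v_test()].
#' @return An object of class `circular_result`: a list with elements
#'   `angles` (wrapped to (-pi, pi]), `n`, `mean_direction`,
#'   `mean_resultant_length`, `circular_dispersion`, `statistic`,
#'   `p_value` and `test`.
NULL

circular_result <- function(angles, mean_direction, mean_resultant_length,
                            circular_dispersion, statistic, p_value, test) {
  structure(
    list(
      angles = angles,
      n = length(angles),
      mean_direction = mean_direction,
      mean_resultant_length = mean_resultant_length,
      circular_dispersion = circular_dispersion,
      statistic = statistic,
      p_value = p_value,
      test = test
    ),
    class = "circular_result"
  )
}

#' @export
print.circular_result <- function(x, ...) {
  cat(sprintf(
    "Circular summary (n = %d): mean direction %.1f deg, R-bar %.3f\n",
    x$n, x$mean_direction * 180 / pi, x$mean_resultant_length))
  cat(sprintf("  circular SD %.1f deg; %s test: statistic %.3f, p = %.4g\n",
              x$circular_dispersion * 180 / pi, x$test, x$statistic,
              x$p_value))
  invisible(x)
}

circ_summary <- function(angles) {
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  rbar <- sqrt(C^2 + S^2)
  list(mean_direction = atan2(S, C),
       rbar = rbar,
       circ_sd = sqrt(pmax(0, -2 * log(pmax(rbar, .Machine$double.xmin)))))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that a sample of angles is uniform on the
#' circle against a unimodal alternative. The p-value uses the standard
#' second-order series approximation
#' \deqn{p \approx e^{-Z}\left[1 + \frac{2Z - Z^2}{4n}
#'   - \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\right]}
#' with \eqn{Z = n \bar R^2}, clamped to \eqn{[0, 1]}.
#'
#' @param angles numeric vector of angles in radians, length >= 4.
#' @return A [circular_result] with `test = "rayleigh"`.
#' @references Mardia, K.V. & Jupp, P.E. (2000) Directional Statistics.
#' @export
rayleigh_test <- function(angles) {
  angles <- check_angles(angles)
  n <- length(angles)
  s <- circ_summary(angles)
  Z <- n * s$rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  circular_result(angles, s$mean_direction, s$rbar, s$circ_sd,
                  statistic = Z, p_value = min(1, max(0, p)),
                  test = "rayleigh")
}

#' V test (modified Rayleigh) toward an expected direction
#'
#' Tests circular uniformity against concentration around a known
#' expected direction. The statistic is
#' \eqn{V = \bar R \cos(\bar\theta - \theta_0)}, standardised as
#' \eqn{u = V\sqrt{2n}} with a one-sided standard normal upper-tail
#' p-value.
#'
#' @inheritParams rayleigh_test
#' @param expected_direction hypothesised mean direction in radians.
#' @return A [circular_result] with `test = "v_test"`; `statistic` is
#'   the standardised `u`.
#' @export
v_test <- function(angles, expected_direction = 0) {
  angles <- check_angles(angles)
  stopifnot(length(expected_direction) == 1L, is.finite(expected_direction))
  n <- length(angles)
  s <- circ_summary(angles)
  V <- s$rbar * cos(s$mean_direction - expected_direction)
  u <- V * sqrt(2 * n)
  circular_result(angles, s$mean_direction, s$rbar, s$circ_sd,
                  statistic = u,
                  p_value = stats::pnorm(u, lower.tail = FALSE),
                  test = "v_test")
}

check_angles <- function(angles, min_n = 4L) {
  angles <- as.numeric(angles)
  if (any(!is.finite(angles))) {
    stop("`angles` must be finite", call. = FALSE)
  }
  if (length(angles) < min_n) {
    stop(sprintf("at least %d angles are required, got %d",
                 min_n, length(angles)), call. = FALSE)
  }
  wrap_angle(angles)
}
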