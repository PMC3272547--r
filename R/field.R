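#' Attractant concentration at a point
#'
#' Concentration of a secreted chemoattractant at `x`, modelled as the
#' quasi-static superposition of one exponential plume per source cell:
#' \deqn{C(x) = \sum_j \exp(-\|x - s_j\| / \lambda)}
#' The field has no explicit production/decay dynamics; every source
#' contributes a unit-amplitude plume with length scale `lambda_coa`.
#'
#' @param x numeric length-2, evaluation point (micrometres).
#' @param sources numeric matrix with 2 columns, one source position per
#'   row. A zero-row matrix (or `NULL`) yields concentration 0.
#' @param lambda_coa attractant decay length scale in micrometres (> 0).
#' @return Non-negative scalar concentration (arbitrary units).
#' @seealso [attractant_gradient()]
#' @export
#' @examples
#' attractant_concentration(c(0, 0), rbind(c(10, 0)), lambda_coa = 10)
attractant_concentration <- function(x, sources, lambda_coa) {
  check_lambda(lambda_coa)
  sources <- as_source_matrix(sources)
  if (nrow(sources) == 0L) return(0)
  d <- sqrt((sources[, 1] - x[1])^2 + (sources[, 2] - x[2])^2)
  sum(exp(-d / lambda_coa))
}

#' Attractant gradient at a point
#'
#' Analytic spatial gradient of the exponential-sum attractant field of
#' [attractant_concentration()]. Sources closer to `x` than
#' `self_exclusion_radius` are omitted so that a cell does not steer
#' toward its own secretion (the self plume is singular in direction at
#' the cell's own position).
#'
#' @inheritParams attractant_concentration
#' @param self_exclusion_radius sources within this distance of `x` are
#'   ignored (micrometres, >= 0). Default 0 retains every source.
#' @return Numeric length-2 gradient vector; `c(0, 0)` when no sources
#'   are retained.
#' @export
attractant_gradient <- function(x, sources, lambda_coa,
                                self_exclusion_radius = 0) {
  check_lambda(lambda_coa)
  stopifnot(self_exclusion_radius >= 0)
  sources <- as_source_matrix(sources)
  if (nrow(sources) == 0L) return(c(0, 0))
  dx <- x[1] - sources[, 1]
  dy <- x[2] - sources[, 2]
  d <- sqrt(dx^2 + dy^2)
  keep <- d > self_exclusion_radius
  if (!any(keep)) return(c(0, 0))
  dx <- dx[keep]; dy <- dy[keep]; d <- d[keep]
  w <- -exp(-d / lambda_coa) / (lambda_coa * d)
  c(sum(w * dx), sum(w * dy))
}

check_lambda <- function(lambda_coa) {
  if (!is.numeric(lambda_coa) || length(lambda_coa) != 1L ||
      !is.finite(lambda_coa) || lambda_coa <= 0) {
    stop("`lambda_coa` must be a single positive number", call. = FALSE)
  }
  invisible(lambda_coa)
}

as_source_matrix <- function(sources) {
  if (is.null(sources)) return(matrix(numeric(0), 0L, 2L))
  if (is.vector(sources) && length(sources) == 2L) sources <- rbind(sources)
  sources <- as.matrix(sources)
  if (nrow(sources) > 0L && ncol(sources) != 2L) {
    stop("`sources` must have two columns (x, y)", call. = FALSE)
  }
  storage.mode(sources) <- "double"
  sources
}
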