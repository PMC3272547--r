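#' Delaunay-triangulation dispersion of a point set
#'
#' Size-independent dispersion measure for a snapshot of cell
#' positions. For each cell the Delaunay triangulation of the point set
#' supplies its natural neighbours; the cell's dispersion is the area of
#' the triangle formed with its two closest Delaunay neighbours. Crowded
#' cells form small triangles, scattered cells large ones, and because
#' the measure is local it does not depend on the overall size of the
#' explant. The summary scalar is the median of the per-cell areas.
#'
#' Neighbour selection is deterministic: the closest neighbour is taken
#' first (ties by lowest point index); when several remaining
#' neighbours tie for second-closest (within 1e-9 relative, as on a
#' regular lattice) the tie is resolved in favour of the candidate
#' giving the largest triangle area, so collinear neighbour pairs are
#' never preferred over equally near non-collinear ones.
#'
#' @param points numeric matrix (or data frame) with columns x, y; at
#'   least 3 non-collinear, duplicate-free points.
#' @return An object of class `dispersion_result`: list with
#'   `per_cell_areas` (micrometres squared, one per input point),
#'   `summary` (their median), `n_cells`, and `neighbours` (integer
#'   matrix of the two selected neighbour indices per point).
#' @export
#' @examples
#' eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
#' delaunay_dispersion(eq)$summary  # sqrt(3)/4
delaunay_dispersion <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2L) stop("`points` needs x and y columns", call. = FALSE)
  pts <- pts[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 3L) stop("at least 3 points are required", call. = FALSE)
  if (anyDuplicated(pts)) {
    stop("duplicate points: jitter or deduplicate before calling",
         call. = FALSE)
  }
  if (is_collinear(pts)) {
    stop("points are collinear; dispersion is undefined", call. = FALSE)
  }
  adj <- delaunay_adjacency(pts)
  nb <- matrix(NA_integer_, n, 2L)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    cand <- adj[[i]]
    sel <- nearest_two(pts, i, cand)
    nb[i, ] <- sel
    areas[i] <- triangle_area(pts[i, ], pts[sel[1L], ], pts[sel[2L], ])
  }
  structure(
    list(per_cell_areas = areas,
         summary = stats::median(areas),
         n_cells = n,
         neighbours = nb),
    class = "dispersion_result"
  )
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(
    "Delaunay dispersion of %d cells: median triangle area %.2f um^2\n",
    x$n_cells, x$summary))
  cat(sprintf("  per-cell range [%.2f, %.2f]\n",
              min(x$per_cell_areas), max(x$per_cell_areas)))
  invisible(x)
}

## Delaunay adjacency lists via deldir
delaunay_adjacency <- function(pts) {
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  seg <- dd$delsgs
  adj <- vector("list", nrow(pts))
  for (k in seq_len(nrow(seg))) {
    i <- seg$ind1[k]; j <- seg$ind2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

## two closest neighbours among candidates, with the tie-break
## documented in delaunay_dispersion()
nearest_two <- function(pts, i, cand) {
  if (length(cand) < 2L) {
    stop("point has fewer than two triangulation neighbours", call. = FALSE)
  }
  d <- sqrt((pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2)
  o <- order(d, cand)
  first <- cand[o[1L]]
  rest <- cand[o[-1L]]
  drest <- d[o[-1L]]
  tied <- which(drest <= drest[1L] * (1 + 1e-9))
  if (length(tied) > 1L) {
    areas <- vapply(rest[tied], function(j) {
      triangle_area(pts[i, ], pts[first, ], pts[j, ])
    }, numeric(1))
    second <- rest[tied][which.max(areas)]
  } else {
    second <- rest[1L]
  }
  c(first, second)
}

triangle_area <- function(a, b, c) {
  abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) / 2
}

is_collinear <- function(pts, tol = 1e-12) {
  a <- pts[1, ]
  rel <- sweep(pts[-1, , drop = FALSE], 2, a)
  scale <- max(abs(rel))
  if (scale == 0) return(TRUE)
  cross <- rel[1, 1] * rel[, 2] - rel[1, 2] * rel[, 1]
  all(abs(cross) / scale^2 < tol)
}
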