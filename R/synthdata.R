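#' Generate biased random-walk tracks
#'
#' Synthetic 2-D cell tracks with analytically known directional
#' statistics, emulating time-lapse tracking output: each step has
#' fixed length and a heading drawn from a von Mises distribution
#' about a drift direction. The drift is either a fixed angle or, in
#' pursuit mode, recomputed each step toward a stationary target (the
#' way a cell tracks a fixed chemoattractant source). `kappa = 0`
#' gives isotropic walks. The mean cosine of the step deviations about
#' the drift has the closed form \eqn{I_1(\kappa)/I_0(\kappa)}.
#'
#' @param n_tracks number of tracks.
#' @param n_steps steps per track (track length is `n_steps + 1`).
#' @param step_length step length in micrometres (> 0).
#' @param drift_direction drift angle in radians; ignored when `target`
#'   is given.
#' @param target optional length-2 point; drift is recomputed toward it
#'   at every step (pursuit mode).
#' @param kappa von Mises concentration of step angles about the drift
#'   (>= 0; 0 = isotropic).
#' @param start_region list describing where tracks start:
#'   `list(type = "disc", centre =, radius =)` or
#'   `list(type = "annulus", centre =, r_in =, r_out =)`. Starting
#'   points are drawn uniformly by area.
#' @param dt time step in minutes.
#' @param group group label for all generated tracks.
#' @param seed integer seed; the output is fully determined by it.
#' @return A [track_set()]; metadata records the generating parameters.
#' @export
gen_biased_walks <- function(n_tracks, n_steps, step_length = 2,
                             drift_direction = 0, target = NULL,
                             kappa = 0,
                             start_region = list(type = "disc",
                                                 centre = c(0, 0),
                                                 radius = 0),
                             dt = 1, group = "1", seed = 1) {
  stopifnot(n_tracks >= 1, n_steps >= 1, step_length > 0, kappa >= 0)
  set.seed(as.integer(seed))
  starts <- sample_start_region(n_tracks, start_region)
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    pos <- matrix(0, n_steps + 1L, 2L)
    pos[1L, ] <- starts[i, ]
    for (s in seq_len(n_steps)) {
      mu <- if (is.null(target)) {
        drift_direction
      } else {
        atan2(target[2] - pos[s, 2], target[1] - pos[s, 1])
      }
      ang <- rvonmises(1L, mu, kappa)
      pos[s + 1L, ] <- pos[s, ] + step_length * c(cos(ang), sin(ang))
    }
    rows[[i]] <- data.frame(track_id = sprintf("w%03d", i),
                            t = (0:n_steps) * dt,
                            x = pos[, 1], y = pos[, 2],
                            group = group)
  }
  track_set(do.call(rbind, rows),
            metadata = list(generator = "biased_walk", kappa = kappa,
                            step_length = step_length,
                            drift_direction = drift_direction,
                            target = target, seed = seed))
}

sample_start_region <- function(n, region) {
  type <- region$type %||% "disc"
  centre <- region$centre %||% c(0, 0)
  if (type == "disc") {
    r_out <- region$radius %||% 0
    r_in <- 0
  } else if (type == "annulus") {
    r_in <- region$r_in
    r_out <- region$r_out
    if (is.null(r_in) || is.null(r_out) || r_in >= r_out) {
      stop("annulus needs r_in < r_out", call. = FALSE)
    }
  } else {
    stop("unknown start region type: ", type, call. = FALSE)
  }
  if (r_out == 0) {
    return(matrix(rep(centre, each = n), n, 2L))
  }
  r <- sqrt(stats::runif(n, r_in^2, r_out^2))
  th <- stats::runif(n, -pi, pi)
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

#' Generate a jittered hexagonal point cloud
#'
#' Point pattern standing in for a snapshot of cell positions in an
#' explant: the `n_points` sites of a hexagonal lattice (lattice
#' constant `spacing`) closest to `centre`, each displaced by a uniform
#' jitter. With `jitter = 0` the two nearest Delaunay neighbours of an
#' interior point span an equilateral triangle of area
#' \eqn{(\sqrt 3 / 4)\,\mathrm{spacing}^2}, giving
#' [delaunay_dispersion()] an exact reference value; points remain
#' duplicate-free for any `jitter < 1`.
#'
#' @param n_points number of points (>= 3).
#' @param spacing lattice constant in micrometres (> 0).
#' @param jitter fraction of `spacing` in [0, 1); each coordinate is
#'   perturbed by Uniform(-jitter*spacing/2, +jitter*spacing/2).
#' @param centre cloud centre.
#' @param seed integer seed.
#' @return Numeric matrix with columns `x`, `y`.
#' @export
gen_point_cloud <- function(n_points, spacing = 50, jitter = 0,
                            centre = c(0, 0), seed = 1) {
  stopifnot(n_points >= 3, spacing > 0, jitter >= 0, jitter < 1)
  set.seed(as.integer(seed))
  k <- ceiling(sqrt(n_points)) + 3L
  ij <- expand.grid(i = -k:k, j = -k:k)
  x <- spacing * (ij$i + 0.5 * (ij$j %% 2))
  y <- spacing * (sqrt(3) / 2) * ij$j
  ord <- order(x^2 + y^2, ij$j, ij$i)
  sel <- ord[seq_len(n_points)]
  pts <- cbind(x = centre[1] + x[sel], y = centre[2] + y[sel])
  if (jitter > 0) {
    pts <- pts + matrix(stats::runif(2L * n_points,
                                     -jitter * spacing / 2,
                                     jitter * spacing / 2),
                        n_points, 2L)
  }
  pts
}

#' Generate two confronted explant snapshots
#'
#' Two point clouds with centroids a fixed distance apart, emulating
#' the two-explant confrontation geometry (explants cultured in close
#' proximity without physical contact). Partner directions (the unit
#' vector from each cloud centre toward the other) are attached for
#' coattraction-vector analysis.
#'
#' @param separation centroid-to-centroid distance in micrometres.
#' @param n_points,spacing,jitter,seed per-cloud parameters as in
#'   [gen_point_cloud()] (each cloud gets its own seed derived from
#'   `seed`).
#' @return List with `cloud1`, `cloud2` (point matrices), `centres`,
#'   `partner_direction` (2 x 2 matrix, row i = unit vector from cloud
#'   i toward the other), and `separation`.
#' @export
gen_two_explant_snapshot <- function(separation = 500, n_points = 40,
                                     spacing = 50, jitter = 0, seed = 1) {
  ## cloud radius of the hexagonal disc, used for the overlap guard
  radius <- spacing * (sqrt(n_points / pi / (sqrt(3) / 2)) + 1)
  if (separation <= 2 * radius) {
    stop(sprintf(
      "separation %.0f would overlap clouds of radius %.0f", separation,
      radius), call. = FALSE)
  }
  c1 <- c(-separation / 2, 0)
  c2 <- c(+separation / 2, 0)
  cloud1 <- gen_point_cloud(n_points, spacing, jitter, c1, seed = seed)
  cloud2 <- gen_point_cloud(n_points, spacing, jitter, c2,
                            seed = seed + 1L)
  list(cloud1 = cloud1, cloud2 = cloud2,
       centres = rbind(c1, c2),
       partner_direction = rbind(c(1, 0), c(-1, 0)),
       separation = separation)
}
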