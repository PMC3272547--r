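#' Chemotaxis index of a track
#'
#' Cosine of the angle between a track's net displacement (last minus
#' first position) and the direction from its start toward an
#' attractant source: 1 for migration straight at the source, 0 for
#' orthogonal movement, -1 for migration straight away.
#'
#' @param track either a two-column position matrix (time-ordered) or
#'   an element of [split_tracks()].
#' @param source length-2 position of the attractant source.
#' @return Scalar in [-1, 1].
#' @export
chemotaxis_index <- function(track, source) {
  pos <- track_positions(track)
  disp <- pos[nrow(pos), ] - pos[1L, ]
  to_source <- source - pos[1L, ]
  nd <- sqrt(sum(disp^2))
  ns <- sqrt(sum(to_source^2))
  if (nd == 0) stop("zero net displacement: chemotaxis index undefined",
                    call. = FALSE)
  if (ns == 0) stop("track starts at the source: chemotaxis index undefined",
                    call. = FALSE)
  sum(disp * to_source) / (nd * ns)
}

#' Directional persistence of a track
#'
#' Net displacement magnitude divided by total path length: 1 for a
#' straight path, 0 for a path returning exactly to its start.
#'
#' @inheritParams chemotaxis_index
#' @return Scalar in [0, 1].
#' @export
persistence <- function(track) {
  pos <- track_positions(track)
  steps <- diff(pos)
  path <- sum(sqrt(rowSums(steps^2)))
  if (path == 0) stop("zero path length: persistence undefined",
                      call. = FALSE)
  net <- sqrt(sum((pos[nrow(pos), ] - pos[1L, ])^2))
  net / path
}

#' Coattraction vector of confronted explants
#'
#' Net displacement of each track (or each group of tracks) expressed
#' as an angle relative to the direction toward the partner explant,
#' summarised with circular statistics and tested for directional bias
#' toward the partner with a V test (expected direction 0).
#'
#' @param tracks a [track_set()].
#' @param partner_direction length-2 vector pointing toward the partner
#'   explant; defines angle 0.
#' @param by `"track"` for one angle per cell track, `"group"` for one
#'   angle per group of tracks (the net displacement of the group mean
#'   position, one angle per explant).
#' @return List with `circ` (a [circular_result] from the V test),
#'   `mean_displacement` (mean net displacement vector, micrometres)
#'   and `angles`. Tracks with zero net displacement are dropped with a
#'   warning.
#' @export
coattraction_vector <- function(tracks, partner_direction,
                                by = c("track", "group")) {
  by <- match.arg(by)
  stopifnot(length(partner_direction) == 2L,
            sum(partner_direction^2) > 0)
  ref <- atan2(partner_direction[2], partner_direction[1])
  tl <- split_tracks(tracks)
  if (by == "group") {
    groups <- split(tl, vapply(tl, `[[`, "", "group"))
    disp <- t(vapply(groups, function(g) {
      d <- vapply(g, function(tr) {
        p <- tr$positions
        p[nrow(p), ] - p[1L, ]
      }, numeric(2))
      rowMeans(d)
    }, numeric(2)))
  } else {
    disp <- t(vapply(tl, function(tr) {
      p <- tr$positions
      p[nrow(p), ] - p[1L, ]
    }, numeric(2)))
  }
  mag <- sqrt(rowSums(disp^2))
  if (any(mag == 0)) {
    warning(sum(mag == 0), " track(s) with zero net displacement dropped")
    disp <- disp[mag > 0, , drop = FALSE]
  }
  angles <- wrap_angle(atan2(disp[, 2], disp[, 1]) - ref)
  circ <- if (length(angles) >= 4L) {
    v_test(angles, 0)
  } else {
    ## too few angles for a calibrated test: summary only
    s <- circ_summary(angles)
    circular_result(angles, s$mean_direction, s$rbar, s$circ_sd,
                    statistic = NA_real_, p_value = NA_real_,
                    test = "none")
  }
  list(circ = circ,
       mean_displacement = unname(colMeans(disp)),
       angles = angles)
}

#' Angular deviation from the group's average direction
#'
#' Coherence statistic for a co-migrating group. At each time point the
#' average direction is the direction of the vector mean of all
#' per-track step displacements; each track's deviation angle theta is
#' its step direction relative to that average. Reported per time
#' point: the deviation angles, their circular standard deviation and
#' the interquartile range of the wrapped angles. Time points where
#' fewer than two tracks move are skipped with a warning.
#'
#' @param tracks a [track_set()]; tracks must share time points to
#'   contribute jointly.
#' @return List with `times`, `theta` (list of deviation-angle vectors
#'   per time point), `circ_sd` (radians) and `iqr` (radians).
#' @export
angular_deviation <- function(tracks) {
  stopifnot(nrow(tracks) > 0L)
  df <- as.data.frame(tracks)
  df <- df[order(df$track_id, df$t), ]
  idx <- split(seq_len(nrow(df)), df$track_id)
  if (length(idx) < 2L) stop("need at least 2 tracks", call. = FALSE)
  steps <- do.call(rbind, lapply(idx, function(i) {
    if (length(i) < 2L) return(NULL)
    data.frame(t = df$t[i[-length(i)]],
               dx = diff(df$x[i]), dy = diff(df$y[i]))
  }))
  steps <- steps[steps$dx != 0 | steps$dy != 0, , drop = FALSE]
  times <- sort(unique(steps$t))
  theta <- list(); circ_sd <- numeric(0); iqr <- numeric(0); kept <- numeric(0)
  skipped <- 0L
  for (tt in times) {
    s <- steps[steps$t == tt, , drop = FALSE]
    if (nrow(s) < 2L) { skipped <- skipped + 1L; next }
    avg <- atan2(sum(s$dy), sum(s$dx))
    th <- wrap_angle(atan2(s$dy, s$dx) - avg)
    kept <- c(kept, tt)
    theta <- c(theta, list(th))
    rb <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    circ_sd <- c(circ_sd, sqrt(max(0, -2 * log(max(rb, .Machine$double.xmin)))))
    iqr <- c(iqr, diff(stats::quantile(th, c(0.25, 0.75), names = FALSE)))
  }
  if (skipped > 0L) {
    warning(skipped, " time point(s) with fewer than 2 moving tracks skipped")
  }
  list(times = kept, theta = theta, circ_sd = circ_sd, iqr = iqr)
}

#' Proximal/distal directional bias toward a cluster
#'
#' Strata analysis of scattered single-cell tracks around a cell
#' cluster: every per-step displacement is assigned to the proximal
#' (starting distance < `threshold`) or distal (>= `threshold`)
#' stratum; step angles are measured relative to the direction toward
#' the cluster centroid. Each non-empty stratum gets a V test toward
#' the centroid (expected direction 0) and a rose histogram.
#'
#' @param tracks a [track_set()] of single-cell tracks.
#' @param centroid length-2 cluster centroid position.
#' @param threshold proximal/distal boundary distance in micrometres;
#'   steps starting exactly at the threshold count as distal.
#' @param bins number of rose-plot bins (default 18, i.e. 20 degrees).
#' @return List with one element per stratum (`proximal`, `distal`):
#'   each is `NULL` when empty, otherwise a list with `circ` (V test),
#'   `angles`, `n_steps` and `rose` (named bin counts).
#' @export
proximal_distal_bias <- function(tracks, centroid, threshold = 300,
                                 bins = 18L) {
  stopifnot(length(centroid) == 2L, threshold > 0, bins >= 4L)
  tl <- split_tracks(tracks)
  ang <- list(proximal = numeric(0), distal = numeric(0))
  for (tr in tl) {
    p <- tr$positions
    if (nrow(p) < 2L) next
    for (s in seq_len(nrow(p) - 1L)) {
      from <- p[s, ]; to <- p[s + 1L, ]
      if (all(to == from)) next
      dist0 <- sqrt(sum((from - centroid)^2))
      toward <- atan2(centroid[2] - from[2], centroid[1] - from[1])
      a <- wrap_angle(atan2(to[2] - from[2], to[1] - from[1]) - toward)
      key <- if (dist0 < threshold) "proximal" else "distal"
      ang[[key]] <- c(ang[[key]], a)
    }
  }
  lapply(ang, function(a) {
    if (length(a) == 0L) return(NULL)
    list(circ = if (length(a) >= 4L) v_test(a, 0) else NULL,
         angles = a,
         n_steps = length(a),
         rose = rose_counts(a, bins))
  })
}

rose_counts <- function(angles, bins = 18L) {
  breaks <- seq(-pi, pi, length.out = bins + 1L)
  a <- wrap_angle(angles)
  a[a == pi] <- -pi  # put the +pi boundary in the first bin
  counts <- table(cut(a, breaks, include.lowest = TRUE, right = FALSE))
  stats::setNames(as.integer(counts),
                  sprintf("[%.0f,%.0f)", breaks[-length(breaks)] * 180 / pi,
                          breaks[-1L] * 180 / pi))
}

track_positions <- function(track) {
  pos <- if (is.list(track) && !is.null(track$positions)) {
    track$positions
  } else {
    as.matrix(track)
  }
  if (ncol(pos) != 2L || nrow(pos) < 2L) {
    stop("a track needs >= 2 rows of (x, y) positions", call. = FALSE)
  }
  storage.mode(pos) <- "double"
  pos
}
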