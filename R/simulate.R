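#' Contact-inhibition repulsion on one agent
#'
#' Sum over all other agents within the contact radius `r_cil` of the
#' unit vector pointing from the neighbour toward the focal agent: the
#' instantaneous repolarisation away from cell-cell contacts that
#' emulates contact inhibition of locomotion. Exactly coincident pairs
#' repel along a random direction drawn from the current R random
#' stream.
#'
#' @param agent_index index of the focal agent.
#' @param positions n x 2 matrix of agent positions.
#' @param r_cil contact radius, micrometres (> 0).
#' @return Length-2 repulsion vector (zero when no neighbour is in
#'   contact).
#' @export
cil_repulsion <- function(agent_index, positions, r_cil) {
  stopifnot(r_cil > 0)
  positions <- as.matrix(positions)
  dx <- positions[agent_index, 1] - positions[, 1]
  dy <- positions[agent_index, 2] - positions[, 2]
  d <- sqrt(dx^2 + dy^2)
  d[agent_index] <- Inf
  out <- c(0, 0)
  contact <- which(d < r_cil)
  for (j in contact) {
    if (d[j] == 0) {
      th <- stats::runif(1, -pi, pi)
      out <- out + c(cos(th), sin(th))
    } else {
      out <- out + c(dx[j], dy[j]) / d[j]
    }
  }
  out
}

#' Create the initial simulation state
#'
#' Agents are hexagonally packed at `init_spacing` (about one cell
#' diameter): a disc around the origin for the unbounded arena, two
#' discs with centroids `separation` apart (groups "1" and "2") for the
#' confrontation arena, and a block packed within the corridor width
#' with its top row just under the corridor top for the corridor arena.
#' Headings are uniform random. Consumes the R random stream.
#'
#' @param config a [sim_config()].
#' @return A `sim_state`: list with `time`, `positions` (n x 2),
#'   `headings` (n x 2 unit rows), `group` (character) and `arrived`
#'   (logical).
#' @export
init_state <- function(config) {
  sp <- config$init_spacing
  ar <- config$arena
  if (ar$type == "confrontation") {
    p1 <- hex_disc(config$n_agents, sp, c(-ar$separation / 2, 0))
    p2 <- hex_disc(config$n_agents, sp, c(+ar$separation / 2, 0))
    pos <- rbind(p1, p2)
    group <- rep(c("1", "2"), each = config$n_agents)
  } else if (ar$type == "corridor") {
    pos <- hex_block(config$n_agents, sp, ar$width,
                     ar$length - (ar$release_depth %||% 0))
    group <- rep("1", config$n_agents)
  } else {
    pos <- hex_disc(config$n_agents, sp, c(0, 0))
    group <- rep("1", config$n_agents)
  }
  n <- nrow(pos)
  th <- stats::runif(n, -pi, pi)
  structure(
    list(time = 0,
         positions = pos,
         headings = cbind(cos(th), sin(th)),
         group = group,
         arrived = rep(FALSE, n),
         refractory = rep(0L, n)),
    class = "sim_state"
  )
}

## hexagonally packed disc of n points around `centre`
hex_disc <- function(n, spacing, centre) {
  k <- ceiling(sqrt(n)) + 3L
  ij <- expand.grid(i = -k:k, j = -k:k)
  x <- spacing * (ij$i + 0.5 * (ij$j %% 2))
  y <- spacing * (sqrt(3) / 2) * ij$j
  ord <- order(x^2 + y^2, ij$j, ij$i)
  sel <- ord[seq_len(n)]
  pts <- cbind(centre[1] + x[sel], centre[2] + y[sel])
  pts[, 1] <- pts[, 1] - mean(pts[, 1]) + centre[1]
  pts[, 2] <- pts[, 2] - mean(pts[, 2]) + centre[2]
  pts
}

## hexagonal block packed within a corridor of width W, top row at y_top
hex_block <- function(n, spacing, W, y_top) {
  ncol <- max(2L, floor((W - spacing) / spacing) + 1L)
  nrow <- ceiling(n / ncol)
  pts <- NULL
  for (r in seq_len(nrow) - 1L) {
    off <- if (r %% 2L) spacing / 2 else 0
    xs <- (seq_len(ncol) - 1L) * spacing + off
    pts <- rbind(pts, cbind(xs, y_top - r * spacing * sqrt(3) / 2))
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  pts[, 1] <- pts[, 1] + (W - max(pts[, 1]) - min(pts[, 1])) / 2
  unname(pts)
}

#' Apply arena boundary rules to one agent
#'
#' Corridor rules: a proposed position beyond a side or top wall is
#' specularly reflected and the corresponding heading component
#' flipped; a position entering the bottom strip (y <= target_depth)
#' is clamped to the strip boundary and the agent marked `arrived`
#' (arrived agents never move again). Unbounded and confrontation
#' arenas impose no constraint.
#'
#' @param position proposed length-2 position.
#' @param heading length-2 unit heading.
#' @param arena an arena description (see [arena_corridor()]).
#' @return List with `position`, `heading`, `arrived`.
#' @export
apply_arena <- function(position, heading, arena) {
  if (!identical(arena$type, "corridor")) {
    return(list(position = position, heading = heading, arrived = FALSE))
  }
  x <- position[1]; y <- position[2]
  hx <- heading[1]; hy <- heading[2]
  for (i in 1:10) {
    moved <- FALSE
    if (x < 0) { x <- -x; hx <- -hx; moved <- TRUE }
    if (x > arena$width) { x <- 2 * arena$width - x; hx <- -hx; moved <- TRUE }
    if (y > arena$length) { y <- 2 * arena$length - y; hy <- -hy; moved <- TRUE }
    if (!moved) break
  }
  arrived <- y <= arena$target_depth
  if (arrived) y <- arena$target_depth
  list(position = c(x, y), heading = c(hx, hy), arrived = arrived)
}

#' Advance the simulation by one step
#'
#' For every non-arrived agent the new heading direction is
#' \deqn{\mathrm{normalize}(w_p h_{old} + n_{rand} + w_{cil} R +
#'   w_{coa} \hat g)}
#' where \eqn{n_{rand}} is a unit vector at a von Mises angle centred
#' on the old heading (concentration `noise_kappa`), \eqn{R} is the
#' contact repulsion of [cil_repulsion()] and \eqn{\hat g} the unit
#' attractant gradient of [attractant_gradient()] over all other
#' agents' positions (zero when the gradient vanishes). The agent then
#' advances exactly `speed * dt` along the new heading and arena rules
#' are applied. A numerically zero resultant keeps the previous
#' heading. All agents remain attractant sources and contact obstacles
#' after arrival; arrived agents no longer move.
#'
#' @param state a `sim_state` from [init_state()].
#' @param config the [sim_config()].
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state, config) {
  n <- nrow(state$positions)
  cfg <- list(speed = config$speed, dt = config$dt, r_cil = config$r_cil,
              lambda_coa = config$lambda_coa, w_cil = config$w_cil,
              w_coa = config$w_coa, w_persist = config$w_persist,
              noise_kappa = config$noise_kappa,
              cil_persist_steps = config$cil_persist_steps,
              cil_persist_gain = config$cil_persist_gain,
              self_exclusion_radius = config$self_exclusion_radius,
              arena_type = config$arena$type,
              arena_width = config$arena$width %||% 0,
              arena_length = config$arena$length %||% 0,
              arena_target_depth = config$arena$target_depth %||% 0)
  out <- .engine_step(state$positions, state$headings, state$arrived,
                      state$refractory %||% rep(0L, n), cfg)
  structure(
    list(time = state$time + config$dt,
         positions = out$positions,
         headings = out$headings,
         group = state$group,
         arrived = out$arrived,
         refractory = out$refractory),
    class = "sim_state"
  )
}

#' Run the agent-based migration model
#'
#' Seeds the R random stream with `config$seed`, initialises the
#' cluster(s) with [init_state()] and advances [sim_step()]
#' `config$n_steps` times, recording every agent at every time point.
#' Identical configurations (including the seed) give bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return A `sim_result` list:
#'   * `tracks`: a [track_set()] with one row per agent and time point
#'     (columns `track_id,t,x,y,group,arrived`);
#'   * `arrival_fraction`: fraction of agents arrived at the corridor
#'     target by the final step (0 outside the corridor arena);
#'   * `centroid_distance`: data frame `t`, `distance` of the
#'     inter-centroid distance of the two groups (confrontation arena
#'     only, otherwise `NULL`);
#'   * `final_state`: the final `sim_state`;
#'   * `config`: the configuration used.
#' @export
run_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- init_state(config)
  n <- nrow(state$positions)
  steps <- config$n_steps
  xs <- matrix(NA_real_, steps + 1L, n)
  ys <- matrix(NA_real_, steps + 1L, n)
  arr <- matrix(FALSE, steps + 1L, n)
  xs[1L, ] <- state$positions[, 1]
  ys[1L, ] <- state$positions[, 2]
  arr[1L, ] <- state$arrived
  for (s in seq_len(steps)) {
    state <- sim_step(state, config)
    xs[s + 1L, ] <- state$positions[, 1]
    ys[s + 1L, ] <- state$positions[, 2]
    arr[s + 1L, ] <- state$arrived
  }
  times <- (0:steps) * config$dt
  df <- data.frame(
    track_id = rep(sprintf("a%03d", seq_len(n)), each = steps + 1L),
    t = rep(times, n),
    x = as.vector(xs),
    y = as.vector(ys),
    group = rep(state$group, each = steps + 1L),
    arrived = as.vector(arr)
  )
  tracks <- track_set(df, metadata = list(config = config_flatten(config)))
  centroid <- NULL
  if (identical(config$arena$type, "confrontation")) {
    g1 <- state$group == "1"
    d <- sqrt((rowMeans(xs[, g1, drop = FALSE]) -
                 rowMeans(xs[, !g1, drop = FALSE]))^2 +
                (rowMeans(ys[, g1, drop = FALSE]) -
                   rowMeans(ys[, !g1, drop = FALSE]))^2)
    centroid <- data.frame(t = times, distance = d)
  }
  structure(
    list(tracks = tracks,
         arrival_fraction = mean(state$arrived),
         centroid_distance = centroid,
         final_state = state,
         config = config),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation (%s arena): %d agents, %d steps\n",
              x$config$arena$type, nrow(x$final_state$positions),
              x$config$n_steps))
  if (identical(x$config$arena$type, "corridor")) {
    cat(sprintf("  arrival fraction %.3f\n", x$arrival_fraction))
  }
  if (!is.null(x$centroid_distance)) {
    cat(sprintf("  inter-centroid distance %.1f -> %.1f um\n",
                x$centroid_distance$distance[1],
                utils::tail(x$centroid_distance$distance, 1)))
  }
  invisible(x)
}

#' Corridor, confrontation and free-field runs
#'
#' Convenience wrappers around [run_model()] that install the matching
#' arena (keeping any arena parameters already set in `config` when the
#' type matches).
#'
#' @param config a [sim_config()]; its arena is replaced as needed.
#' @param ... arena parameters passed to [arena_corridor()] or
#'   [arena_confrontation()] when the config does not already carry the
#'   right arena type.
#' @return A `sim_result`; see [run_model()].
#' @export
simulate_corridor <- function(config = sim_config(), ...) {
  if (!identical(config$arena$type, "corridor")) {
    config$arena <- arena_corridor(...)
    config <- validate_sim_config(config)
  }
  run_model(config)
}

#' @rdname simulate_corridor
#' @export
simulate_confrontation <- function(config = sim_config(), ...) {
  if (!identical(config$arena$type, "confrontation")) {
    config$arena <- arena_confrontation(...)
    config <- validate_sim_config(config)
  }
  run_model(config)
}

#' @rdname simulate_corridor
#' @export
simulate_free <- function(config = sim_config()) {
  if (!identical(config$arena$type, "unbounded")) {
    config$arena <- arena_unbounded()
    config <- validate_sim_config(config)
  }
  run_model(config)
}
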