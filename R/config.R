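#' Arena geometries
#'
#' Three arena types close the model domain:
#'
#' * `arena_corridor()`: a migration corridor of the given `width`
#'   (x in \[0, width\]) and `length` (y in \[0, length\]). Side and top
#'   walls reflect specularly; the strip y <= `target_depth` at the
#'   bottom absorbs: an agent entering it is marked `arrived` and
#'   frozen.
#' * `arena_confrontation()`: unbounded plane; two equal clusters are
#'   initialised with centroids `separation` apart on the x axis.
#' * `arena_unbounded()`: unbounded plane, single cluster.
#'
#' @param width,length corridor size in micrometres.
#' @param target_depth height of the absorbing strip at the corridor
#'   bottom, micrometres.
#' @param release_depth distance from the corridor top to the first row
#'   of the released cluster, micrometres (headroom above the cells).
#' @param separation initial centroid-to-centroid distance of the two
#'   confronted clusters, micrometres.
#' @return A list describing the arena, for [sim_config()].
#' @export
arena_corridor <- function(width = 300, length = 500, target_depth = 40,
                           release_depth = 80) {
  stopifnot(width > 0, length > 0, target_depth > 0, target_depth < length,
            release_depth >= 0, release_depth < length - target_depth)
  list(type = "corridor", width = width, length = length,
       target_depth = target_depth, release_depth = release_depth)
}

#' @rdname arena_corridor
#' @export
arena_confrontation <- function(separation = 500) {
  stopifnot(separation > 0)
  list(type = "confrontation", separation = separation)
}

#' @rdname arena_corridor
#' @export
arena_unbounded <- function() list(type = "unbounded")

#' Simulation configuration
#'
#' Validated record of every model parameter. Defaults place the model
#' in its swarming regime; the qualitative phenotypes are robust to
#' sizeable perturbations of the interaction weights.
#'
#' @param n_agents agents per cluster (the confrontation arena holds
#'   two such clusters).
#' @param speed migration speed, micrometres per minute. Every
#'   non-arrived agent moves exactly `speed * dt` per step.
#' @param dt time step, minutes.
#' @param n_steps number of steps to simulate.
#' @param r_cil contact radius of the short-range repulsion emulating
#'   contact inhibition of locomotion, micrometres.
#' @param lambda_coa decay length of the secreted attractant,
#'   micrometres; must exceed `r_cil` (coattraction acts at longer
#'   range than contact repulsion).
#' @param w_cil weight of the contact-repulsion term (>= 0).
#' @param w_coa weight of the attractant-gradient term (>= 0); 0 is the
#'   coattraction-deficient (morphant-like) configuration.
#' @param w_persist weight of the previous heading (>= 0).
#' @param noise_kappa von Mises concentration of the angular noise
#'   (>= 0; larger = more persistent motion).
#' @param cil_persist_steps duration, in steps, of the repolarised
#'   (refractory) phase that follows a cell-cell contact: while it
#'   lasts, the angular noise concentration is multiplied by
#'   `cil_persist_gain`, so freshly repolarised cells run near-straight
#'   before relaxing to baseline noise. Contacts reset the counter. The
#'   phase belongs to the contact-inhibition machinery and is inactive
#'   when `w_cil = 0`. Set to 0 to disable.
#' @param cil_persist_gain multiplier (>= 1) applied to `noise_kappa`
#'   during the refractory phase.
#' @param init_spacing initial hexagonal packing distance between
#'   agent centres, micrometres; roughly one cell diameter.
#' @param self_exclusion_radius sources closer than this are excluded
#'   from an agent's sensed gradient (defaults to `r_cil / 2`).
#' @param arena an [arena_corridor()], [arena_confrontation()] or
#'   [arena_unbounded()].
#' @param seed integer seed making the run fully reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_agents = 60,
                       speed = 2,
                       dt = 1,
                       n_steps = 500,
                       r_cil = 20,
                       lambda_coa = 200,
                       w_cil = 2,
                       w_coa = 2,
                       w_persist = 1,
                       noise_kappa = 2,
                       cil_persist_steps = 20L,
                       cil_persist_gain = 50,
                       init_spacing = 20,
                       self_exclusion_radius = r_cil / 2,
                       arena = arena_unbounded(),
                       seed = 1L) {
  cfg <- list(n_agents = as.integer(n_agents), speed = speed, dt = dt,
              n_steps = as.integer(n_steps), r_cil = r_cil,
              lambda_coa = lambda_coa, w_cil = w_cil, w_coa = w_coa,
              w_persist = w_persist, noise_kappa = noise_kappa,
              cil_persist_steps = as.integer(cil_persist_steps),
              cil_persist_gain = cil_persist_gain,
              init_spacing = init_spacing,
              self_exclusion_radius = self_exclusion_radius,
              arena = arena, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$n_agents >= 1, "n_agents must be >= 1")
  chk(cfg$speed > 0, "speed must be > 0")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$n_steps >= 0, "n_steps must be >= 0")
  chk(cfg$r_cil > 0, "r_cil must be > 0")
  chk(cfg$lambda_coa > 0, "lambda_coa must be > 0")
  chk(cfg$lambda_coa > cfg$r_cil,
      "lambda_coa must exceed r_cil (attraction is the longer-range interaction)")
  chk(cfg$w_cil >= 0, "w_cil must be >= 0")
  chk(cfg$w_coa >= 0, "w_coa must be >= 0")
  chk(cfg$w_persist >= 0, "w_persist must be >= 0")
  chk(cfg$noise_kappa >= 0, "noise_kappa must be >= 0")
  chk(cfg$cil_persist_steps >= 0, "cil_persist_steps must be >= 0")
  chk(cfg$cil_persist_gain >= 1, "cil_persist_gain must be >= 1")
  chk(cfg$init_spacing > 0, "init_spacing must be > 0")
  chk(cfg$self_exclusion_radius >= 0, "self_exclusion_radius must be >= 0")
  chk(is.list(cfg$arena) && cfg$arena$type %in%
        c("unbounded", "corridor", "confrontation"),
      "arena must be one of unbounded/corridor/confrontation")
  if (identical(cfg$arena$type, "corridor")) {
    chk(cfg$arena$width > 0 && cfg$arena$length > 0 &&
          cfg$arena$target_depth > 0 &&
          cfg$arena$target_depth < cfg$arena$length,
        "corridor needs 0 < target_depth < length and width > 0")
  }
  if (identical(cfg$arena$type, "confrontation")) {
    chk(cfg$arena$separation > 0, "confrontation separation must be > 0")
  }
  if (length(problems) > 0L) {
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  flat <- config_flatten(x)
  for (k in names(flat)) cat(sprintf("  %-22s %s\n", k, flat[[k]]))
  invisible(x)
}

config_flatten <- function(cfg) {
  out <- list()
  for (k in setdiff(names(cfg), "arena")) out[[k]] <- cfg[[k]]
  out$arena <- cfg$arena$type
  for (k in setdiff(names(cfg$arena), "type")) {
    out[[paste0("arena_", k)]] <- cfg$arena[[k]]
  }
  out
}

#' Load a simulation configuration from a flat key-value file
#'
#' Reads lines of the form `key = value` (`#` comments and blank lines
#' ignored). Keys are the [sim_config()] arguments plus the arena
#' sub-keys `arena` (type), `arena_width`, `arena_length`,
#' `arena_target_depth` and `arena_separation`. Every key has a
#' default; unknown keys are an error. `overrides` (e.g. from the
#' command line) take precedence over file values.
#'
#' @param path config file, or `NULL` for pure defaults/overrides.
#' @param overrides named list applied after the file.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) != 3L) {
        stop("cannot parse config line: ", ln, call. = FALSE)
      }
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  kv[names(overrides)] <- overrides
  known_num <- c("n_agents", "speed", "dt", "n_steps", "r_cil",
                 "lambda_coa", "w_cil", "w_coa", "w_persist",
                 "noise_kappa", "cil_persist_steps", "cil_persist_gain",
                 "init_spacing", "self_exclusion_radius",
                 "seed", "arena_width", "arena_length",
                 "arena_target_depth", "arena_release_depth",
                 "arena_separation")
  unknown <- setdiff(names(kv), c(known_num, "arena"))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num <- function(k) if (is.null(kv[[k]])) NULL else as.numeric(kv[[k]])
  atype <- kv[["arena"]] %||% "unbounded"
  arena <- switch(
    atype,
    unbounded = arena_unbounded(),
    corridor = {
      a <- arena_corridor()
      if (!is.null(num("arena_width"))) a$width <- num("arena_width")
      if (!is.null(num("arena_length"))) a$length <- num("arena_length")
      if (!is.null(num("arena_target_depth")))
        a$target_depth <- num("arena_target_depth")
      if (!is.null(num("arena_release_depth")))
        a$release_depth <- num("arena_release_depth")
      a
    },
    confrontation = {
      a <- arena_confrontation()
      if (!is.null(num("arena_separation")))
        a$separation <- num("arena_separation")
      a
    },
    stop("unknown arena type: ", atype, call. = FALSE)
  )
  args <- list(arena = arena)
  for (k in setdiff(known_num,
                    c("arena_width", "arena_length", "arena_target_depth",
                      "arena_release_depth", "arena_separation"))) {
    if (!is.null(num(k))) args[[k]] <- num(k)
  }
  do.call(sim_config, args)
}
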