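#' In-silico phenotype experiments
#'
#' The two seed-matched experiments that exhibit the model's core
#' phenotypes, packaged so they can be reproduced with one call.
#'
#' `corridor_phenotype_experiment()` runs, for every seed, three
#' corridor simulations sharing all parameters except the interaction
#' weights: *none* (w_cil = 0, w_coa = 0), *CIL only* (w_coa = 0) and
#' *CIL + CoA*. It reports the arrival fraction of each condition and
#' the end-point Delaunay dispersion (median per-cell two-neighbour
#' triangle area over the still-migrating, i.e. non-arrived, agents).
#' Contact inhibition alone disperses the cluster but transports cells
#' to the target efficiently; adding coattraction keeps the group
#' cohesive.
#'
#' `confrontation_phenotype_experiment()` runs, for every seed, a
#' two-cluster confrontation with coattraction on and off. It reports
#' initial and final inter-centroid distance, the linear-fit slope of
#' the centroid-distance series for the CoA-off run, and the V-test
#' p-value of each run's per-cell net displacements toward the partner
#' cluster. With coattraction the clusters approach each other; without
#' it they do not.
#'
#' @param seeds integer vector of seeds, one triplet/pair of runs each.
#' @param w_cil,w_coa,lambda_coa,noise_kappa model parameters for the
#'   interacting conditions (the *none* condition always has both
#'   weights 0 but shares `noise_kappa`).
#' @param n_steps steps per run.
#' @param n_agents agents per confronted cluster (the corridor
#'   experiment uses the [sim_config()] default). Confronted explants
#'   are larger than a migratory stream segment, so the confrontation
#'   default is 100 agents per cluster.
#' @param arena arena for the corridor experiment.
#' @param separation confrontation separation, micrometres.
#' @param reuse optional result of a previous call whose conditions
#'   match for some runs (same seeds assumed): columns named in
#'   `reuse_cols` are copied instead of recomputed. Used to avoid
#'   re-running conditions that do not depend on a perturbed parameter.
#' @param reuse_cols character vector of column prefixes to copy from
#'   `reuse` (`"none"`, `"cil"` for the corridor; `"off"` for the
#'   confrontation).
#' @return A data frame with one row per seed.
#' @export
corridor_phenotype_experiment <- function(seeds = 1:20,
                                          w_cil = 2, w_coa = 2,
                                          lambda_coa = 200,
                                          noise_kappa = 2,
                                          n_steps = 500,
                                          arena = arena_corridor(),
                                          reuse = NULL,
                                          reuse_cols = character(0)) {
  one <- function(sd) {
    row <- list(seed = sd)
    conds <- list(
      none = c(0, 0),
      cil = c(w_cil, 0),
      coa = c(w_cil, w_coa)
    )
    for (nm in names(conds)) {
      if (nm %in% reuse_cols && !is.null(reuse)) {
        i <- match(sd, reuse$seed)
        row[[paste0("arrival_", nm)]] <- reuse[[paste0("arrival_", nm)]][i]
        row[[paste0("dispersion_", nm)]] <-
          reuse[[paste0("dispersion_", nm)]][i]
        next
      }
      res <- run_model(sim_config(w_cil = conds[[nm]][1],
                                  w_coa = conds[[nm]][2],
                                  lambda_coa = lambda_coa,
                                  noise_kappa = noise_kappa,
                                  n_steps = n_steps,
                                  arena = arena, seed = sd))
      st <- res$final_state
      free <- st$positions[!st$arrived, , drop = FALSE]
      row[[paste0("arrival_", nm)]] <- res$arrival_fraction
      row[[paste0("dispersion_", nm)]] <-
        if (nrow(free) >= 3) delaunay_dispersion(free)$summary else NA_real_
    }
    as.data.frame(row)
  }
  do.call(rbind, lapply(seeds, one))
}

#' @rdname corridor_phenotype_experiment
#' @export
confrontation_phenotype_experiment <- function(seeds = 1:20,
                                               w_cil = 2, w_coa = 2,
                                               lambda_coa = 200,
                                               noise_kappa = 2,
                                               n_steps = 800,
                                               n_agents = 100,
                                               separation = 500,
                                               reuse = NULL,
                                               reuse_cols = character(0)) {
  one <- function(sd) {
    run_one <- function(w_coa_run) {
      run_model(sim_config(n_agents = n_agents,
                           w_cil = w_cil, w_coa = w_coa_run,
                           lambda_coa = lambda_coa,
                           noise_kappa = noise_kappa,
                           n_steps = n_steps,
                           arena = arena_confrontation(separation),
                           seed = sd))
    }
    partner_p <- function(res) {
      st <- res$final_state
      df <- res$tracks
      ini <- df[df$t == 0, ]
      fin <- df[df$t == max(df$t), ]
      disp <- cbind(fin$x - ini$x, fin$y - ini$y)
      ## group 1 sits left of group 2: partner direction +x / -x
      ref <- ifelse(ini$group == "1", 0, pi)
      ang <- wrap_angle(atan2(disp[, 2], disp[, 1]) - ref)
      v_test(ang, 0)$p_value
    }
    on <- run_one(w_coa)
    cd_on <- on$centroid_distance$distance
    row <- list(seed = sd,
                initial_distance = cd_on[1],
                final_distance = cd_on[length(cd_on)],
                p_on = partner_p(on))
    if ("off" %in% reuse_cols && !is.null(reuse)) {
      i <- match(sd, reuse$seed)
      row$slope_off <- reuse$slope_off[i]
      row$p_off <- reuse$p_off[i]
    } else {
      off <- run_one(0)
      cd_off <- off$centroid_distance$distance
      row$slope_off <- stats::coef(
        stats::lm(cd_off ~ seq_along(cd_off)))[[2]]
      row$p_off <- partner_p(off)
    }
    as.data.frame(row)
  }
  do.call(rbind, lapply(seeds, one))
}
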