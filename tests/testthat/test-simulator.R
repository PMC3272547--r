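cfg_small <- function(...) {
  sim_config(n_agents = 12, n_steps = 30, seed = 42, ...)
}

test_that("cil repulsion follows the pairwise geometry", {
  ## isolated agent
  expect_equal(cil_repulsion(1, rbind(c(0, 0), c(100, 0)), r_cil = 20),
               c(0, 0))
  ## one pair at half the contact radius
  pos <- rbind(c(0, 0), c(10, 0))
  expect_equal(cil_repulsion(1, pos, 20), c(-1, 0))
  expect_equal(cil_repulsion(2, pos, 20), c(1, 0))
  ## four symmetric contacts cancel
  pos4 <- rbind(c(0, 0), c(10, 0), c(-10, 0), c(0, 10), c(0, -10))
  expect_equal(cil_repulsion(1, pos4, 20), c(0, 0), tolerance = 1e-12)
  ## coincident pair: random unit direction
  set.seed(1)
  r <- cil_repulsion(1, rbind(c(5, 5), c(5, 5)), 20)
  expect_equal(sqrt(sum(r^2)), 1, tolerance = 1e-12)
})

test_that("agent count is conserved and speed is exactly constant", {
  cfg <- cfg_small(w_cil = 2, w_coa = 1)
  res <- run_model(cfg)
  df <- as.data.frame(res$tracks)
  expect_equal(length(unique(df$track_id)), cfg$n_agents)
  expect_equal(nrow(df), cfg$n_agents * (cfg$n_steps + 1))
  step_len <- cfg$speed * cfg$dt
  for (tr in split_tracks(res$tracks)) {
    d <- sqrt(rowSums(diff(tr$positions)^2))
    expect_equal(d, rep(step_len, length(d)), tolerance = 1e-9)
  }
})

test_that("identical seeds give bit-identical tracks, different seeds differ", {
  a <- run_model(cfg_small())
  b <- run_model(cfg_small())
  expect_identical(as.data.frame(a$tracks), as.data.frame(b$tracks))
  c <- run_model(sim_config(n_agents = 12, n_steps = 30, seed = 43))
  expect_false(identical(as.data.frame(a$tracks)$x,
                         as.data.frame(c$tracks)$x))
})

test_that("a lone agent with no noise moves in a straight line", {
  cfg <- sim_config(n_agents = 1, n_steps = 25, w_cil = 0, w_coa = 0,
                    noise_kappa = 1e8, seed = 5)
  res <- run_model(cfg)
  tr <- split_tracks(res$tracks)[[1]]
  net <- sqrt(sum((tr$positions[nrow(tr$positions), ] -
                     tr$positions[1, ])^2))
  expect_equal(net, cfg$n_steps * cfg$speed * cfg$dt, tolerance = 1e-6)
})

test_that("strong contact repulsion separates a close pair", {
  cfg <- sim_config(n_agents = 2, n_steps = 1, w_cil = 50, w_coa = 0,
                    w_persist = 0, noise_kappa = 0, seed = 2)
  state <- structure(
    list(time = 0,
         positions = rbind(c(0, 0), c(10, 0)),
         headings = rbind(c(0, 1), c(0, 1)),
         group = c("1", "1"),
         arrived = c(FALSE, FALSE)),
    class = "sim_state")
  set.seed(2)
  s2 <- sim_step(state, cfg)
  d0 <- 10
  d1 <- sqrt(sum((s2$positions[1, ] - s2$positions[2, ])^2))
  expect_gt(d1, d0)
})

test_that("arena rules reflect at walls and absorb at the target", {
  ar <- arena_corridor(width = 100, length = 300, target_depth = 30)
  ## beyond the left wall
  out <- apply_arena(c(-2, 150), c(-1, 0), ar)
  expect_equal(out$position, c(2, 150))
  expect_equal(out$heading, c(1, 0))
  expect_false(out$arrived)
  ## into the target strip
  out2 <- apply_arena(c(50, 25), c(0, -1), ar)
  expect_true(out2$arrived)
  expect_equal(out2$position[2], 30)
  ## interior point unchanged
  out3 <- apply_arena(c(50, 150), c(0, 1), ar)
  expect_equal(out3$position, c(50, 150))
  expect_false(out3$arrived)
  ## no constraints off-corridor
  expect_false(apply_arena(c(-100, -100), c(0, 1),
                           arena_unbounded())$arrived)
})

test_that("arrived agents freeze for the rest of the run", {
  cfg <- sim_config(n_agents = 20, n_steps = 150, seed = 11, w_coa = 0,
                    arena = arena_corridor(width = 120, length = 180,
                                           target_depth = 60))
  res <- run_model(cfg)
  df <- as.data.frame(res$tracks)
  arr_ids <- unique(df$track_id[df$arrived])
  expect_gt(length(arr_ids), 0)  # short corridor: some arrivals
  for (id in arr_ids) {
    tr <- df[df$track_id == id, ]
    first_arr <- min(which(tr$arrived))
    after <- tr[first_arr:nrow(tr), ]
    expect_true(all(after$x == after$x[1]))
    expect_true(all(after$y == after$y[1]))
    expect_true(all(after$arrived))
  }
  expect_equal(res$arrival_fraction, length(arr_ids) / 20)
})

test_that("corridor agents stay inside the walls", {
  cfg <- sim_config(n_agents = 15, n_steps = 120, seed = 3,
                    arena = arena_corridor(width = 90, length = 400,
                                           target_depth = 40))
  df <- as.data.frame(run_model(cfg)$tracks)
  expect_true(all(df$x >= 0 & df$x <= 90))
  expect_true(all(df$y <= 400 & df$y >= 40 - 1e-9))
})

test_that("confrontation runs report the centroid-distance series", {
  cfg <- sim_config(n_agents = 10, n_steps = 40, seed = 9,
                    arena = arena_confrontation(separation = 400))
  res <- run_model(cfg)
  cd <- res$centroid_distance
  expect_equal(nrow(cd), 41)
  expect_equal(cd$distance[1], 400, tolerance = 1)
  expect_equal(sort(unique(as.data.frame(res$tracks)$group)), c("1", "2"))
})

test_that("zero-step runs produce single-point tracks and no arrivals", {
  cfg <- sim_config(n_agents = 8, n_steps = 0, seed = 1,
                    arena = arena_corridor())
  res <- run_model(cfg)
  expect_equal(res$arrival_fraction, 0)
  expect_true(all(table(as.data.frame(res$tracks)$track_id) == 1))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(lambda_coa = 10, r_cil = 20), "lambda_coa")
  expect_error(sim_config(speed = 0), "speed")
  expect_silent(sim_config(w_coa = 0))  # morphant analogue is legal
  expect_error(sim_config(arena = list(type = "sphere")), "arena")
})

test_that("the update rule is mirror-symmetric in the deterministic limit", {
  ## two agents in contact, no noise: reflecting the configuration about
  ## the y axis mirrors the trajectories exactly
  cfg <- sim_config(n_agents = 2, n_steps = 5, w_cil = 3, w_coa = 1,
                    noise_kappa = 1e9, seed = 7)
  mk <- function(flip) {
    s <- structure(
      list(time = 0,
           positions = rbind(c(-6 * flip, 0), c(6 * flip, 3)),
           headings = rbind(c(flip * sqrt(0.5), sqrt(0.5)),
                            c(-flip * sqrt(0.5), sqrt(0.5))),
           group = c("1", "1"),
           arrived = c(FALSE, FALSE)),
      class = "sim_state")
    set.seed(7)
    for (i in 1:5) s <- sim_step(s, cfg)
    s$positions
  }
  p <- mk(1)
  q <- mk(-1)
  expect_equal(p[, 1], -q[, 1], tolerance = 1e-3)
  expect_equal(p[, 2], q[, 2], tolerance = 1e-3)
})
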