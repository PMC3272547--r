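test_that("biased walks are deterministic under seed and vary across seeds", {
  a <- gen_biased_walks(5, 20, kappa = 2, seed = 7)
  b <- gen_biased_walks(5, 20, kappa = 2, seed = 7)
  c <- gen_biased_walks(5, 20, kappa = 2, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a)$x, as.data.frame(c)$x))
})

test_that("degenerate concentration gives straight unit-persistence walks", {
  ts <- gen_biased_walks(3, 50, step_length = 2, drift_direction = pi / 3,
                         kappa = 1e6, seed = 1)
  for (tr in split_tracks(ts)) {
    expect_equal(persistence(tr), 1, tolerance = 1e-6)
    net <- tr$positions[nrow(tr$positions), ] - tr$positions[1, ]
    expect_equal(atan2(net[[2]], net[[1]]), pi / 3, tolerance = 1e-3)
  }
})

test_that("step angles reproduce the von Mises Bessel-ratio mean cosine", {
  for (kappa in c(0, 2)) {
    ts <- gen_biased_walks(1, 4000, drift_direction = 0.5, kappa = kappa,
                           seed = 3)
    tr <- split_tracks(ts)[[1]]
    steps <- diff(tr$positions)
    dev <- wrap_angle(atan2(steps[, 2], steps[, 1]) - 0.5)
    expect_equal(mean(cos(dev)),
                 besselI(kappa, 1) / besselI(kappa, 0),
                 tolerance = 0.03)
  }
})

test_that("pursuit mode homes in on the target", {
  tgt <- c(200, 150)
  ts <- gen_biased_walks(4, 400, step_length = 2, target = tgt, kappa = 8,
                         seed = 5)
  for (tr in split_tracks(ts)) {
    endd <- sqrt(sum((tr$positions[nrow(tr$positions), ] - tgt)^2))
    startd <- sqrt(sum((tr$positions[1, ] - tgt)^2))
    expect_lt(endd, startd / 5)
    expect_gt(chemotaxis_index(tr, tgt), 0.8)
  }
})

test_that("start regions are respected", {
  ts <- gen_biased_walks(40, 1, kappa = 0, seed = 2,
                         start_region = list(type = "annulus",
                                             centre = c(10, -5),
                                             r_in = 50, r_out = 80))
  starts <- t(vapply(split_tracks(ts), function(tr) tr$positions[1, ],
                     numeric(2)))
  d <- sqrt((starts[, 1] - 10)^2 + (starts[, 2] + 5)^2)
  expect_true(all(d >= 50 & d <= 80))
  expect_error(gen_biased_walks(2, 2, start_region = list(
    type = "annulus", centre = c(0, 0), r_in = 9, r_out = 3)), "r_in")
})

test_that("point clouds are duplicate-free, jitter-bounded and seeded", {
  p0 <- gen_point_cloud(30, spacing = 50, jitter = 0.2, seed = 4)
  p1 <- gen_point_cloud(30, spacing = 50, jitter = 0.2, seed = 4)
  expect_identical(p0, p1)
  expect_equal(anyDuplicated(p0), 0L)
  base <- gen_point_cloud(30, spacing = 50, jitter = 0, seed = 4)
  expect_true(all(abs(p0 - base) <= 0.2 * 50 / 2 + 1e-12))
})

test_that("two-explant snapshots have the requested geometry", {
  sn <- gen_two_explant_snapshot(500, n_points = 30, spacing = 50,
                                 jitter = 0, seed = 1)
  cd <- sqrt(sum((colMeans(sn$cloud1) - colMeans(sn$cloud2))^2))
  expect_equal(cd, 500, tolerance = 2)  # lattice centring offset only
  expect_equal(sn$partner_direction[1, ], c(1, 0))
  expect_equal(sn$partner_direction[2, ], c(-1, 0))
  expect_error(gen_two_explant_snapshot(100, n_points = 60, spacing = 50),
               "overlap")
  ## per-cloud dispersion is unaffected by the partner cloud
  d1 <- delaunay_dispersion(sn$cloud1)
  solo <- delaunay_dispersion(gen_point_cloud(30, 50, 0, seed = 1,
                                              centre = c(-250, 0)))
  expect_equal(d1$summary, solo$summary, tolerance = 1e-9)
})

test_that("isotropic walk persistence approaches the sqrt(pi)/(2 sqrt(n)) limit", {
  set.seed(17)
  ts <- gen_biased_walks(400, 100, step_length = 1, kappa = 0, seed = 19)
  p <- vapply(split_tracks(ts), persistence, numeric(1))
  expect_equal(mean(p), sqrt(pi) / (2 * sqrt(100)), tolerance = 0.08)
})
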