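test_that("chemotaxis index covers the toward/orthogonal/away extremes", {
  src <- c(0, 0)
  expect_equal(chemotaxis_index(rbind(c(100, 0), c(50, 0)), src), 1)
  expect_equal(chemotaxis_index(rbind(c(100, 0), c(100, 50)), src), 0)
  expect_equal(chemotaxis_index(rbind(c(100, 0), c(150, 0)), src), -1)
  expect_error(chemotaxis_index(rbind(c(100, 0), c(100, 0)), src),
               "zero net displacement")
  expect_error(chemotaxis_index(rbind(c(0, 0), c(1, 1)), c(0, 0)),
               "starts at the source")
})

test_that("chemotaxis index is invariant under time resampling", {
  set.seed(5)
  pts <- apply(matrix(stats::rnorm(20), 10, 2), 2, cumsum)
  src <- c(30, -20)
  ## dropping interior points preserves the net displacement
  expect_equal(chemotaxis_index(pts, src),
               chemotaxis_index(pts[c(1, 4, 10), ], src))
})

test_that("persistence is net displacement over path length", {
  expect_equal(persistence(rbind(c(0, 0), c(1, 0), c(2, 0), c(5, 0))), 1)
  loop <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(persistence(loop), 0)
  tri <- rbind(c(0, 0), c(3, 0), c(3, 4))
  expect_equal(persistence(tri), 5 / 7)
  expect_error(persistence(rbind(c(1, 1), c(1, 1))), "zero path")
})

test_that("persistence and chemotaxis index stay in range on random walks", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    pts <- apply(matrix(stats::rnorm(2 * n, sd = 3), n, 2), 2, cumsum)
    p <- persistence(pts)
    expect_gte(p, 0); expect_lte(p, 1)
    ci <- chemotaxis_index(pts, c(100, 100))
    expect_gte(ci, -1); expect_lte(ci, 1)
  }
})

test_that("coattraction vector detects aligned displacement", {
  ## four tracks moving straight along the partner direction
  df <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(track_id = paste0("t", i), t = 0:3,
               x = (0:3) * 10, y = i)
  }))
  cv <- coattraction_vector(track_set(df), partner_direction = c(1, 0))
  expect_equal(cv$circ$mean_resultant_length, 1, tolerance = 1e-12)
  expect_equal(cv$circ$mean_direction, 0, tolerance = 1e-12)
  expect_equal(cv$mean_displacement, c(30, 0), tolerance = 1e-12)

  ## +90/-90 in equal numbers: V statistic zero
  df2 <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(track_id = paste0("t", i), t = 0:1, x = 0,
               y = c(0, ifelse(i %% 2 == 0, 10, -10)))
  }))
  cv2 <- coattraction_vector(track_set(df2), partner_direction = c(1, 0))
  expect_equal(cv2$circ$statistic, 0, tolerance = 1e-9)
  expect_gt(cv2$circ$p_value, 0.4)
})

test_that("coattraction vector supports per-group mode and drops still tracks", {
  df <- rbind(
    data.frame(track_id = "a1", t = 0:1, x = c(0, 5), y = 0, group = "g1"),
    data.frame(track_id = "a2", t = 0:1, x = c(0, 3), y = c(0, 1), group = "g1"),
    data.frame(track_id = "b1", t = 0:1, x = c(50, 46), y = 0, group = "g2"),
    data.frame(track_id = "b2", t = 0:1, x = c(50, 44), y = c(0, -1), group = "g2"),
    data.frame(track_id = "b3", t = 0:1, x = c(50, 45), y = c(1, 0), group = "g2"),
    data.frame(track_id = "b4", t = 0:1, x = c(50, 47), y = c(0, 1), group = "g2")
  )
  cv <- coattraction_vector(track_set(df), c(1, 0), by = "group")
  expect_equal(cv$circ$n, 2L)
  expect_identical(cv$circ$test, "none")  # too few explants for a test

  dfz <- rbind(data.frame(track_id = c("z", "z"), t = 0:1, x = 0, y = 0),
               df[df$group == "g2", 1:4])
  expect_warning(cvz <- coattraction_vector(track_set(dfz), c(1, 0)),
                 "zero net displacement")
  expect_equal(cvz$circ$n, 4L)
})

test_that("angular deviation separates parallel from divergent groups", {
  ## identical parallel tracks: all deviations zero
  df <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(track_id = paste0("p", i), t = 0:5,
               x = 0:5, y = i * 10)
  }))
  ad <- angular_deviation(track_set(df))
  expect_true(all(unlist(ad$theta) == 0))
  expect_true(all(ad$circ_sd == 0))
  expect_equal(length(ad$times), 5L)

  ## two tracks at +-45 degrees about their mean direction
  df2 <- rbind(
    data.frame(track_id = "u", t = 0:1, x = c(0, 1), y = c(0, 1)),
    data.frame(track_id = "v", t = 0:1, x = c(0, 1), y = c(0, -1))
  )
  ad2 <- angular_deviation(track_set(df2))
  expect_equal(sort(ad2$theta[[1]]), c(-pi / 4, pi / 4), tolerance = 1e-12)
  expect_equal(ad2$circ_sd, sqrt(-2 * log(cos(pi / 4))), tolerance = 1e-12)
})

test_that("proximal/distal strata follow the stated boundary convention", {
  centroid <- c(0, 0)
  ## steps starting at 100 um aimed straight at the centroid
  df <- do.call(rbind, lapply(1:6, function(i) {
    th <- i  # scatter around the cluster
    data.frame(track_id = paste0("s", i), t = 0:1,
               x = c(100 * cos(th), 90 * cos(th)),
               y = c(100 * sin(th), 90 * sin(th)))
  }))
  pd <- proximal_distal_bias(track_set(df), centroid, threshold = 300)
  expect_null(pd$distal)
  expect_equal(pd$proximal$n_steps, 6L)
  expect_lt(pd$proximal$circ$p_value, 0.001)
  expect_equal(sum(pd$proximal$rose), 6L)

  ## a step starting exactly at the threshold counts as distal
  df2 <- data.frame(track_id = "e", t = 0:1, x = c(300, 280), y = 0)
  pd2 <- proximal_distal_bias(track_set(df2), centroid, threshold = 300)
  expect_null(pd2$proximal)
  expect_equal(pd2$distal$n_steps, 1L)
  expect_null(pd2$distal$circ)  # too few angles for a test
})

test_that("trajectory statistics are rotation and translation invariant", {
  set.seed(33)
  pts <- apply(matrix(stats::rnorm(30), 15, 2), 2, cumsum)
  src <- c(12, -7)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(100, -50)
  pts2 <- sweep(pts %*% R, 2, -shift)
  src2 <- as.vector(src %*% R) + shift
  expect_equal(chemotaxis_index(pts, src), chemotaxis_index(pts2, src2),
               tolerance = 1e-12)
  expect_equal(persistence(pts), persistence(pts2), tolerance = 1e-12)
})
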