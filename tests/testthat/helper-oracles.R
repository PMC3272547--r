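## Independent oracles used across the suite.

## Brute-force Delaunay adjacency by the empty-circumcircle test over
## all point triples: a triple forms a Delaunay triangle iff no other
## point lies strictly inside its circumcircle. Degenerate (cocircular)
## inputs are resolved by the strict inequality, matching the
## infinitesimal-perturbation convention.
brute_delaunay_adjacency <- function(pts) {
  n <- nrow(pts)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        cc <- circumcircle(pts[i, ], pts[j, ], pts[k, ])
        if (is.null(cc)) next
        d2 <- (pts[, 1] - cc$centre[1])^2 + (pts[, 2] - cc$centre[2])^2
        d2[c(i, j, k)] <- Inf
        if (all(d2 >= cc$r2 * (1 - 1e-12))) {
          adj[[i]] <- c(adj[[i]], j, k)
          adj[[j]] <- c(adj[[j]], i, k)
          adj[[k]] <- c(adj[[k]], i, j)
        }
      }
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) +
           (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
           (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
  uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) +
           (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
           (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
  list(centre = c(ux, uy), r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
}

## central-difference gradient of the attractant field
fd_gradient <- function(x, sources, lambda, h = 1e-5) {
  c((attractant_concentration(x + c(h, 0), sources, lambda) -
       attractant_concentration(x - c(h, 0), sources, lambda)) / (2 * h),
    (attractant_concentration(x + c(0, h), sources, lambda) -
       attractant_concentration(x - c(0, h), sources, lambda)) / (2 * h))
}

## quick track builder
make_track <- function(xy, dt = 1) {
  xy <- as.matrix(xy)
  track_set(data.frame(track_id = "t1", t = seq_len(nrow(xy)) * dt - dt,
                       x = xy[, 1], y = xy[, 2]))
}
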