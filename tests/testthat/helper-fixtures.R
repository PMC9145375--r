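# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately written as naive loops / alternative formulations, never
# calling the implementation they check.

# Star-shaped random closed mesh: icosphere with radial jitter (valid
# topology for any jitter < 1).
jittered_icosphere <- function(seed, subdivisions = 2, jitter = 0.15) {
  ic <- icosphere(subdivisions)
  set.seed(seed)
  r <- 1 + runif(nrow(ic$vertices), -jitter, jitter)
  ic$vertices <- ic$vertices * r
  ic
}

# Random one-ring fan: neighbors at sorted azimuths around the z axis with
# random radii and heights, center near the origin. Cyclic order holds by
# construction.
random_ring <- function(seed, m = NULL) {
  set.seed(seed)
  if (is.null(m)) m <- sample(5:9, 1)
  ang <- sort(runif(m, 0, 2 * pi))
  rad <- runif(m, 0.5, 1.5)
  q <- cbind(rad * cos(ang), rad * sin(ang), runif(m, -0.3, 0.3))
  list(p = c(runif(2, -0.1, 0.1), runif(1, 0.2, 0.6)), q = q, m = m)
}

## ---- operator oracles (naive re-summation / trigonometric) ----

oracle_umbrella <- function(p, q) {
  s <- c(0, 0, 0)
  for (j in seq_len(nrow(q))) s <- s + q[j, ]
  s / nrow(q) - p
}

oracle_scale_dep <- function(p, q) {
  E <- 0
  s <- c(0, 0, 0)
  len <- numeric(nrow(q))
  for (j in seq_len(nrow(q))) {
    len[j] <- sqrt(sum((q[j, ] - p)^2))
    E <- E + len[j]
  }
  for (j in seq_len(nrow(q))) s <- s + (q[j, ] - p) / len[j]
  2 / E * s
}

# scalar angle-by-angle recomputation (explicit cross product, stable
# two-argument arctangent; the implementation path is vectorized)
oracle_cot_angle <- function(apex, a, b) {
  u <- a - apex
  w <- b - apex
  cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  ang <- atan2(sqrt(sum(cr^2)), sum(u * w))
  ang <- max(pi / 180, min(pi - pi / 180, ang))
  1 / tan(ang)
}

oracle_cotangent <- function(p, q) {
  m <- nrow(q)
  A <- 0
  s <- c(0, 0, 0)
  for (j in seq_len(m)) {
    jn <- if (j == m) 1L else j + 1L
    jp <- if (j == 1L) m else j - 1L
    u <- q[j, ] - p
    w <- q[jn, ] - p
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    A <- A + 0.5 * sqrt(sum(cr^2))
    cot_a <- oracle_cot_angle(q[jn, ], p, q[j, ])
    cot_b <- oracle_cot_angle(q[jp, ], p, q[j, ])
    s <- s + (cot_a + cot_b) * (q[j, ] - p)
  }
  s / (4 * (A / 3))
}

oracle_inv_dist <- function(p, q) {
  w <- numeric(nrow(q))
  for (j in seq_len(nrow(q))) w[j] <- 1 / sqrt(sum((q[j, ] - p)^2))
  w / sum(w)
}

## ---- exact point-triangle distance oracle (candidate enumeration) ----

oracle_point_triangle <- function(p, a, b, c) {
  cands <- list(a, b, c)
  # edge projections, clamped
  for (e in list(list(a, b), list(b, c), list(c, a))) {
    d <- e[[2]] - e[[1]]
    t <- sum((p - e[[1]]) * d) / sum(d^2)
    cands[[length(cands) + 1]] <- e[[1]] + max(0, min(1, t)) * d
  }
  # interior projection via barycentric coordinates
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  n2 <- sum(n^2)
  if (n2 > 0) {
    proj <- p - sum((p - a) * n) / n2 * n
    # barycentric test
    v0 <- c - a; v1 <- b - a; v2 <- proj - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    if (den > 0) {
      u <- (d11 * d20 - d01 * d21) / den
      v <- (d00 * d21 - d01 * d20) / den
      if (u >= 0 && v >= 0 && u + v <= 1)
        cands[[length(cands) + 1]] <- proj
    }
  }
  min(vapply(cands, function(x) sqrt(sum((p - x)^2)), 0))
}

oracle_point_mesh <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  apply(points, 1, function(p) {
    best <- Inf
    for (i in seq_len(nrow(f)))
      best <- min(best, oracle_point_triangle(p, v[f[i, 1], ], v[f[i, 2], ],
                                              v[f[i, 3], ]))
    best
  })
}

# Voxel-count volume of the unit sphere: exact center counting per (x, y)
# column at spacing h.
oracle_sphere_voxel_volume <- function(h = 0.02) {
  half <- ceiling(1 / h) + 1
  cxy <- (seq(-half, half - 1) + 0.5) * h
  g <- expand.grid(x = cxy, y = cxy)
  r2 <- 1 - g$x^2 - g$y^2
  ok <- r2 > 0
  zmax <- sqrt(r2[ok])
  counts <- pmax(0, floor(zmax / h - 0.5) + 1) * 2
  sum(counts) * h^3
}
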