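#' One-ring adjacency of a closed triangle mesh
#'
#' For every vertex i, the ordered one-ring neighborhood N1(i): neighbor
#' indices in cyclic (fan) order obtained by walking the incident triangles,
#' together with per-neighbor edge lengths |e_ij| (mm) and the two angles
#' opposite each edge in the two triangles sharing it (alpha_j, beta_j,
#' radians). The fan walk follows face orientation, so ordering is
#' deterministic up to the starting neighbor, which is fixed to the smallest
#' neighbor index.
#'
#' @param mesh a valid closed `triangle_mesh`.
#' @return An object of class `one_ring`: a list with `neighbors` (list of
#'   integer vectors, cyclic order), `edge_lengths`, `alpha`, `beta` (lists of
#'   numeric vectors aligned with `neighbors`), and `degree` (integer vector
#'   m per vertex).
#' @export
build_adjacency <- function(mesh) {
  validate_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)

  # successor map around each center vertex: face (i,j,k) contributes,
  # at center i, the step j -> k (counter-clockwise seen from outside)
  centers <- c(f[, 1L], f[, 2L], f[, 3L])
  from    <- c(f[, 2L], f[, 3L], f[, 1L])
  to      <- c(f[, 3L], f[, 1L], f[, 2L])
  ord <- order(centers)
  centers <- centers[ord]; from <- from[ord]; to <- to[ord]
  starts <- c(1L, which(diff(centers) > 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(centers))
  if (length(starts) != nv)
    abort_topology("isolated vertex: every vertex must have incident faces")

  neighbors <- vector("list", nv)
  for (i in seq_len(nv)) {
    idx <- starts[i]:ends[i]
    fr <- from[idx]; t2 <- to[idx]
    m <- length(fr)
    start <- min(fr)
    ring <- integer(m)
    cur <- start
    for (s in seq_len(m)) {
      ring[s] <- cur
      nxt <- t2[match(cur, fr)]
      if (is.na(nxt))
        abort_topology(sprintf("broken triangle fan around vertex %d", i))
      cur <- nxt
    }
    if (cur != start || anyDuplicated(ring))
      abort_topology(sprintf("one-ring of vertex %d does not close into a single cycle", i))
    neighbors[[i]] <- ring
  }

  geo <- ring_geometry(v, neighbors)
  structure(list(neighbors = neighbors,
                 edge_lengths = geo$edge_lengths,
                 alpha = geo$alpha,
                 beta = geo$beta,
                 degree = lengths(neighbors)),
            class = "one_ring")
}

# Edge lengths and opposite angles for cyclically ordered rings.
# For neighbor q_s of center p: the edge (p, q_s) is opposite the angle at
# q_{s+1} in triangle (p, q_s, q_{s+1}) [alpha] and the angle at q_{s-1} in
# triangle (p, q_{s-1}, q_s) [beta].
ring_geometry <- function(vertices, neighbors) {
  nv <- length(neighbors)
  el <- vector("list", nv)
  al <- vector("list", nv)
  be <- vector("list", nv)
  for (i in seq_len(nv)) {
    ring <- neighbors[[i]]
    m <- length(ring)
    p <- vertices[i, ]
    q <- vertices[ring, , drop = FALSE]
    d <- sweep(q, 2L, p)
    len <- sqrt(rowSums(d^2))
    if (any(len <= 0)) abort_geometry(sprintf("zero-length edge at vertex %d", i))
    nxt <- c(2:m, 1L)
    prv <- c(m, seq_len(m - 1L))
    al[[i]] <- angle_at(q[nxt, , drop = FALSE], p, q)      # angle at q_{s+1}
    be[[i]] <- angle_at(q[prv, , drop = FALSE], p, q)      # angle at q_{s-1}
    el[[i]] <- len
  }
  list(edge_lengths = el, alpha = al, beta = be)
}

# Angle at apex between directions (a - apex) and (b - apex), rowwise.
angle_at <- function(apex, a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow(apex), 3L, byrow = TRUE)
  u <- a - apex
  w <- b - apex
  du <- sqrt(rowSums(u^2))
  dw <- sqrt(rowSums(w^2))
  cosv <- rowSums(u * w) / (du * dw)
  acos(pmin(1, pmax(-1, cosv)))
}

#' @method print one_ring
#' @export
print.one_ring <- function(x, ...) {
  cat(sprintf("one_ring adjacency: %d vertices, degree %d-%d (mean %.2f)\n",
              length(x$neighbors), min(x$degree), max(x$degree),
              mean(x$degree)))
  invisible(x)
}

# Static per-mesh edge topology used by the iteration drivers: undirected
# edges (i < j) with the two opposite vertices, plus a directed edge list.
mesh_topology <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  de <- cbind(c(f[, 1L], f[, 2L], f[, 3L]),
              c(f[, 2L], f[, 3L], f[, 1L]))
  opp <- c(f[, 3L], f[, 1L], f[, 2L])   # vertex opposite each directed edge
  key <- undirected_edge_key(de, nv)
  ord <- order(key)
  key <- key[ord]; de <- de[ord, , drop = FALSE]; opp <- opp[ord]
  first <- seq(1L, length(key), by = 2L)
  stopifnot(all(key[first] == key[first + 1L]))
  ei <- de[first, 1L]; ej <- de[first, 2L]
  list(nv = nv, faces = f,
       ei = ei, ej = ej,                 # one row per undirected edge
       opp1 = opp[first], opp2 = opp[first + 1L])
}

# Cotangent of the angle at vertex `apex` subtended by i and j, vectorized,
# with the angle clamped to [1, 179] degrees: stair-step meshes contain
# near-degenerate angles whose raw cotangents destabilize curvature flow.
clamped_cot <- function(vertices, apex, i, j) {
  u <- vertices[i, , drop = FALSE] - vertices[apex, , drop = FALSE]
  w <- vertices[j, , drop = FALSE] - vertices[apex, , drop = FALSE]
  dot <- rowSums(u * w)
  crs <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
               u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
               u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  sinv <- sqrt(rowSums(crs^2))
  ang <- atan2(sinv, dot)
  lim <- pi / 180
  ang <- pmin(pi - lim, pmax(lim, ang))
  cos(ang) / sin(ang)
}
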