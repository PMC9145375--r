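#' Local smoothing operators on a one-ring neighborhood
#'
#' The building blocks of the five smoothers, exposed as standalone per-ring
#' functions: the uniform umbrella operator (the discrete Laplacian used by
#' Laplacian smoothing), its scale-dependent variant weighting each neighbor
#' by the inverse connecting edge length, the cotangent estimate of the mean
#' curvature normal, and inverse-distance weights.
#'
#' @param p numeric length-3 position of the center vertex (mm).
#' @param neighbors numeric m x 3 matrix of one-ring neighbor positions; for
#'   `cotangent_curvature_normal` they must be in cyclic (fan) order, as
#'   returned by [build_adjacency()].
#' @return `umbrella` and `scale_dependent_umbrella` return a length-3
#'   displacement vector; `cotangent_curvature_normal` the estimate of
#'   \eqn{-\bar\kappa n} (length-3, pointing opposite the mean-curvature
#'   normal, i.e. inward on a convex surface); `inverse_distance_weights` a
#'   length-m weight vector normalized to sum to 1.
#' @name ring-operators
NULL

#' @rdname ring-operators
#' @export
umbrella <- function(p, neighbors) {
  neighbors <- as_ring_matrix(neighbors)
  if (nrow(neighbors) < 3L)
    abort_topology("umbrella operator needs at least 3 one-ring neighbors")
  colMeans(neighbors) - as.numeric(p)
}

#' @rdname ring-operators
#' @param edge_lengths numeric length-m vector |e_ij| (mm); computed from the
#'   positions when omitted.
#' @export
scale_dependent_umbrella <- function(p, neighbors, edge_lengths = NULL) {
  neighbors <- as_ring_matrix(neighbors)
  if (nrow(neighbors) < 3L)
    abort_topology("scale-dependent umbrella needs at least 3 one-ring neighbors")
  p <- as.numeric(p)
  d <- sweep(neighbors, 2L, p)
  if (is.null(edge_lengths)) edge_lengths <- sqrt(rowSums(d^2))
  if (any(edge_lengths <= 0)) abort_geometry("zero-length edge in one-ring")
  E <- sum(edge_lengths)
  (2 / E) * colSums(d / edge_lengths)
}

#' @rdname ring-operators
#' @details
#' `cotangent_curvature_normal` evaluates
#' \eqn{-\bar\kappa n = \frac{1}{4A}\sum_{j}(\cot\alpha_j+\cot\beta_j)(q_j-p)}
#' where \eqn{\alpha_j,\beta_j} are the two angles opposite the edge to
#' neighbor j in the two incident fan triangles and A is the area of the
#' small region around the vertex: the barycentric cell, one third of the
#' total one-ring triangle area (this normalization recovers the analytic
#' mean curvature, e.g. magnitude 1 on a unit sphere). Angles are clamped to
#' [1, 179] degrees before taking cotangents.
#' @export
cotangent_curvature_normal <- function(p, neighbors) {
  q <- as_ring_matrix(neighbors)
  m <- nrow(q)
  if (m < 3L)
    abort_topology("cotangent operator needs at least 3 one-ring neighbors")
  p <- as.numeric(p)
  nxt <- c(2:m, 1L)
  prv <- c(m, seq_len(m - 1L))
  # fan triangles (p, q_s, q_{s+1}); area via cross products
  u <- sweep(q, 2L, p)
  crs <- cross_rows(u, u[nxt, , drop = FALSE])
  A <- 0.5 * sum(sqrt(rowSums(crs^2))) / 3  # barycentric cell area
  if (A <= 0) abort_geometry("degenerate one-ring: zero total area")
  cot_alpha <- cot_at(q[nxt, , drop = FALSE], p, q)
  cot_beta  <- cot_at(q[prv, , drop = FALSE], p, q)
  w <- cot_alpha + cot_beta
  colSums(u * w) / (4 * A)
}

#' @rdname ring-operators
#' @export
inverse_distance_weights <- function(p, neighbors) {
  neighbors <- as_ring_matrix(neighbors)
  d <- sqrt(rowSums(sweep(neighbors, 2L, as.numeric(p))^2))
  if (any(d <= 0)) abort_geometry("coincident neighbor: inverse-distance weight undefined")
  w <- 1 / d
  w / sum(w)
}

as_ring_matrix <- function(neighbors) {
  neighbors <- as.matrix(neighbors)
  if (ncol(neighbors) != 3L) abort_geometry("neighbors must be an m x 3 matrix")
  storage.mode(neighbors) <- "double"
  neighbors
}

cross_rows <- function(u, w) {
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

# Clamped cotangent of the angle at `apex` rows between a and b rows.
cot_at <- function(apex, a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow(apex), 3L, byrow = TRUE)
  u <- a - apex
  w <- b - apex
  dot <- rowSums(u * w)
  crs <- cross_rows(u, w)
  ang <- atan2(sqrt(rowSums(crs^2)), dot)
  lim <- pi / 180
  ang <- pmin(pi - lim, pmax(lim, ang))
  cos(ang) / sin(ang)
}
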