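#' Smoothing configuration
#'
#' Bundles the method id and all scalar controls for [smooth_mesh()].
#'
#' Methods: `M1` uniform Laplacian (umbrella) smoothing; `M2` Laplacian
#' smoothing with volume-compensating pre-dilation and volume-aware
#' termination; `M3` scale-dependent Laplacian; `M4` cotangent
#' mean-curvature flow (explicit-normalized or implicit backward-Euler
#' integration); `M5` inverse-distance weighted Laplacian. Name aliases
#' `laplacian`, `predilate`, `scaledep`, `curvflow`, `invdist` are accepted.
#'
#' `lambda` is the diffusion step in (0, 1]; for the row-normalized operators
#' (M1, M4 explicit, M5) this is the plain step of the update
#' p <- p + lambda * U(p), and for M3 - whose scale-dependent umbrella is not
#' row-normalized and carries units of 1/mm - the driver rescales the step by
#' the mesh's explicit stability limit each iteration, so lambda retains the
#' meaning "fraction of the stability limit" for every method (see the
#' methods vignette). lambda = 0 is allowed and yields the identity.
#'
#' @param method method id `M1`..`M5` or a name alias (see Details).
#' @param lambda diffusion step in \[0, 1\]; default 0.5.
#' @param dt time step (implicit curvature flow only); default 0.1.
#' @param iterations iteration count for M1, M3, M4, M5 (default 30, the
#'   standard manual termination point) and the dilation-phase smoothing cap
#'   context for M2 reporting.
#' @param dilation_fraction target relative volume increase of the
#'   pre-dilation (default 0.05, i.e. +5\% volume).
#' @param volume_threshold stopping fraction for M2 (default 0.005: stop when
#'   the smoothed volume is back within 0.5\% of the original volume).
#' @param curvature_mode `"explicit"` (normalized explicit integration) or
#'   `"implicit"` (backward Euler) for M4.
#' @param max_iterations hard cap on M2's smoothing loop (default 10000);
#'   hitting it is reported as non-convergence.
#' @return an object of class `smooth_config`.
#' @export
smooth_config <- function(method = c("M1", "M2", "M3", "M4", "M5",
                                     "laplacian", "predilate", "scaledep",
                                     "curvflow", "invdist"),
                          lambda = 0.5, dt = 0.1, iterations = 30L,
                          dilation_fraction = 0.05, volume_threshold = 0.005,
                          curvature_mode = c("explicit", "implicit"),
                          max_iterations = 10000L) {
  choices <- c("M1", "M2", "M3", "M4", "M5", "laplacian", "predilate",
               "scaledep", "curvflow", "invdist")
  if (identical(method, choices)) method <- "M1"
  if (!is.character(method) || length(method) != 1L || !method %in% choices)
    abort_usage(sprintf("unknown method '%s'; use M1..M5 or %s",
                        paste(method, collapse = ","),
                        paste(choices[6:10], collapse = "/")))
  alias <- c(laplacian = "M1", predilate = "M2", scaledep = "M3",
             curvflow = "M4", invdist = "M5")
  if (method %in% names(alias)) method <- unname(alias[method])
  if (length(curvature_mode) > 1L) curvature_mode <- curvature_mode[1L]
  if (!curvature_mode %in% c("explicit", "implicit"))
    abort_usage("curvature_mode must be 'explicit' or 'implicit'")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    abort_usage("lambda must lie in [0, 1] (explicit-update stability guard)")
  if (!is.numeric(dt) || dt <= 0) abort_usage("dt must be positive")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    abort_usage("iterations must be a positive integer")
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L)
    abort_usage("max_iterations must be a positive integer")
  if (method == "M2") {
    if (dilation_fraction <= 0 || dilation_fraction >= 1)
      abort_usage("dilation_fraction must lie in (0, 1) for pre-dilation smoothing")
    if (volume_threshold <= 0 || volume_threshold >= 1)
      abort_usage("volume_threshold must lie in (0, 1)")
    if (volume_threshold >= dilation_fraction)
      abort_usage("volume_threshold must be smaller than dilation_fraction for pre-dilation smoothing to be meaningful")
  } else {
    if (dilation_fraction < 0) abort_usage("dilation_fraction must be nonnegative")
    if (volume_threshold <= 0) abort_usage("volume_threshold must be positive")
  }
  structure(list(method = method, lambda = lambda, dt = dt,
                 iterations = iterations,
                 dilation_fraction = dilation_fraction,
                 volume_threshold = volume_threshold,
                 curvature_mode = curvature_mode,
                 max_iterations = max_iterations),
            class = "smooth_config")
}

#' @method print smooth_config
#' @export
print.smooth_config <- function(x, ...) {
  cat(sprintf("smooth_config: method %s, lambda %g, iterations %d\n",
              x$method, x$lambda, x$iterations))
  if (x$method == "M2")
    cat(sprintf("  dilation %g%%, volume threshold %g%%, cap %d\n",
                100 * x$dilation_fraction, 100 * x$volume_threshold,
                x$max_iterations))
  if (x$method == "M4")
    cat(sprintf("  curvature mode %s%s\n", x$curvature_mode,
                if (x$curvature_mode == "implicit") sprintf(", dt %g", x$dt) else ""))
  invisible(x)
}

#' Dilate a mesh to a target volume increase
#'
#' Moves every vertex by a single offset `alpha` along its unit vertex
#' normal. `alpha` is solved by bisection so that the dilated signed volume
#' equals `(1 + dilation_fraction)` times the original volume to within 1e-6
#' relative; "5\% dilation" is thus read as +5\% enclosed volume, which is the
#' quantity the pre-dilation smoother's own stopping rule monitors (an
#' absolute millimetre offset would be object-size dependent). The solved
#' `alpha` is returned so the literal fixed-offset reading can be reproduced.
#'
#' @param mesh a valid `triangle_mesh`.
#' @param dilation_fraction nonnegative target relative volume increase.
#' @return list with `mesh` (dilated) and `alpha` (mm).
#' @export
dilate_mesh <- function(mesh, dilation_fraction) {
  if (dilation_fraction < 0) abort_usage("dilation_fraction must be nonnegative")
  if (dilation_fraction == 0) return(list(mesh = mesh, alpha = 0))
  v0 <- mesh_volume(mesh)
  if (v0 <= 0) abort_geometry("dilate_mesh needs a positively oriented mesh")
  n <- vertex_normals(mesh)
  target <- (1 + dilation_fraction) * v0
  vol_at <- function(alpha) {
    m2 <- mesh
    m2$vertices <- mesh$vertices + alpha * n
    mesh_volume(m2)
  }
  bb <- apply(mesh$vertices, 2L, range)
  hi <- 2 * sqrt(sum((bb[2L, ] - bb[1L, ])^2))
  lo <- 0
  if (vol_at(hi) < target)
    abort_geometry("dilation bisection cannot bracket the target volume (pathological normals)")
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    vm <- vol_at(mid)
    if (abs(vm - target) <= 1e-6 * target) { lo <- hi <- mid; break }
    if (vm < target) lo <- mid else hi <- mid
  }
  alpha <- (lo + hi) / 2
  out <- mesh
  out$vertices <- mesh$vertices + alpha * n
  if (abs(mesh_volume(out) - target) > 1e-6 * target)
    abort_numerical("dilation bisection did not reach 1e-6 relative volume tolerance")
  list(mesh = out, alpha = alpha)
}

#' Smooth a closed triangle mesh
#'
#' Runs the configured smoothing algorithm. All five methods use
#' simultaneous (Jacobi) updates: every displacement is computed from the
#' previous iterate and applied at once, so results are order-independent and
#' bit-reproducible. Topology (vertex count and face list) is never changed.
#'
#' @param mesh a valid closed `triangle_mesh`.
#' @param config a [smooth_config()].
#' @return An object of class `smooth_result`: list with `mesh` (the smoothed
#'   mesh), `method`, `config`, `volume_log` (signed volume before iteration
#'   1 and after every iteration), `iterations_run`, `termination` (list with
#'   `reason`: `"iterations"` for M1/M3/M4/M5; `"threshold"`, `"contact"` or
#'   `"cap"` for M2, `cap` flagged as non-convergence), and for M2 `alpha`
#'   (the solved dilation offset, mm).
#' @export
smooth_mesh <- function(mesh, config) {
  if (!inherits(config, "smooth_config")) abort_usage("config must be a smooth_config")
  validate_mesh(mesh)
  switch(config$method,
         M1 = smooth_fixed_iterations(mesh, config, step_uniform),
         M2 = smooth_predilated(mesh, config),
         M3 = smooth_fixed_iterations(mesh, config, step_scale_dependent),
         M4 = if (config$curvature_mode == "implicit")
                smooth_fixed_iterations(mesh, config, step_curvature_implicit)
              else smooth_fixed_iterations(mesh, config, step_curvature_explicit),
         M5 = smooth_fixed_iterations(mesh, config, step_inverse_distance))
}

smooth_result <- function(mesh, config, volume_log, iterations_run,
                          reason, alpha = NULL, converged = TRUE) {
  structure(list(mesh = mesh, method = config$method, config = config,
                 volume_log = volume_log, iterations_run = iterations_run,
                 termination = list(reason = reason, converged = converged),
                 alpha = alpha),
            class = "smooth_result")
}

#' @method print smooth_result
#' @export
print.smooth_result <- function(x, ...) {
  cat(sprintf("smooth_result: %s, %d iteration(s), termination: %s\n",
              x$method, x$iterations_run, x$termination$reason))
  v <- x$volume_log
  cat(sprintf("  volume %.6g -> %.6g mm^3 (%+.3g%%)\n",
              v[1L], v[length(v)], 100 * (v[length(v)] / v[1L] - 1)))
  if (!is.null(x$alpha)) cat(sprintf("  dilation offset alpha = %.6g mm\n", x$alpha))
  invisible(x)
}

# Shared fixed-iteration driver for M1, M3, M4, M5.
smooth_fixed_iterations <- function(mesh, config, step_fn) {
  topo <- mesh_topology(mesh)
  p <- mesh$vertices
  vols <- numeric(config$iterations + 1L)
  vols[1L] <- mesh_volume(mesh)
  state <- NULL
  for (it in seq_len(config$iterations)) {
    upd <- step_fn(p, topo, config, state, it)
    p <- upd$p
    state <- upd$state
    m2 <- mesh; m2$vertices <- p
    vols[it + 1L] <- mesh_volume(m2)
  }
  out <- mesh
  out$vertices <- p
  smooth_result(out, config, vols, config$iterations, "iterations")
}

edge_weight_matrix <- function(topo, w) {
  Matrix::sparseMatrix(i = c(topo$ei, topo$ej), j = c(topo$ej, topo$ei),
                       x = c(w, w), dims = c(topo$nv, topo$nv))
}

# M1: p <- p + lambda * (mean of neighbors - p), uniform weights.
step_uniform <- function(p, topo, config, state, it) {
  if (is.null(state)) {
    A <- edge_weight_matrix(topo, rep(1, length(topo$ei)))
    state <- list(A = A, m = Matrix::rowSums(A))
  }
  disp <- as.matrix(state$A %*% p) / state$m - p
  list(p = p + config$lambda * disp, state = state)
}

# M3: scale-dependent umbrella U_i = (2/E_i) sum_j (p_j - p_i)/|e_ij| with
# edge lengths recomputed each iteration; the step is lambda times the
# explicit stability limit 1 / max_i (2/E_i) sum_j 1/|e_ij|.
step_scale_dependent <- function(p, topo, config, state, it) {
  d <- p[topo$ej, , drop = FALSE] - p[topo$ei, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len <= 0)) abort_geometry("zero-length edge during scale-dependent smoothing")
  S <- edge_weight_matrix(topo, 1 / len)
  L <- edge_weight_matrix(topo, len)
  Ei <- Matrix::rowSums(L)
  sumw <- Matrix::rowSums(S)
  U <- (2 / Ei) * (as.matrix(S %*% p) - sumw * p)
  stab <- 1 / max(2 * sumw / Ei)
  list(p = p + config$lambda * stab * U, state = state)
}

# M5: inverse-distance weighted neighbor mean, weights normalized per ring.
step_inverse_distance <- function(p, topo, config, state, it) {
  d <- p[topo$ej, , drop = FALSE] - p[topo$ei, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len <= 0)) abort_geometry("coincident vertices during inverse-distance smoothing")
  W <- edge_weight_matrix(topo, 1 / len)
  rs <- Matrix::rowSums(W)
  disp <- as.matrix(W %*% p) / rs - p
  list(p = p + config$lambda * disp, state = state)
}

cot_edge_weights <- function(p, topo) {
  clamped_cot(p, topo$opp1, topo$ei, topo$ej) +
    clamped_cot(p, topo$opp2, topo$ei, topo$ej)
}

# M4 explicit: cotangent weights normalized to sum to 1 per ring. Negative
# per-edge cotangent sums (obtuse configurations, ubiquitous on stair-step
# meshes) are floored at zero before normalization: with signed weights the
# ring normalizer can approach zero and the normalized update diverges,
# while floored weights make every step a convex combination and hence
# unconditionally stable for lambda <= 1. Rings whose floored weights sum to
# zero receive no displacement (the normalized operator is undefined there).
step_curvature_explicit <- function(p, topo, config, state, it) {
  w <- pmax(cot_edge_weights(p, topo), 0)
  W <- edge_weight_matrix(topo, w)
  rs <- Matrix::rowSums(W)
  safe <- abs(rs) > 1e-12
  disp <- matrix(0, nrow(p), 3L)
  wm <- as.matrix(W %*% p)
  disp[safe, ] <- wm[safe, , drop = FALSE] / rs[safe] - p[safe, , drop = FALSE]
  list(p = p + config$lambda * disp, state = state)
}

# M4 implicit: backward Euler (I - lambda dt K) P' = P with K the cotangent
# curvature-normal matrix, K P = -kappa n (rows scaled by 1/(4 A_i), A_i the
# barycentric cell area = one third of the one-ring area); reassembled from
# the current iterate each iteration.
step_curvature_implicit <- function(p, topo, config, state, it) {
  w <- cot_edge_weights(p, topo)
  W <- edge_weight_matrix(topo, w)
  rs <- Matrix::rowSums(W)
  # one-ring areas: accumulate face areas to their three corners
  fa <- triangle_areas_from(p, topo$faces)
  A <- rowsum(rep(fa, 3L), group = as.vector(topo$faces), reorder = FALSE)
  Ai <- numeric(topo$nv)
  Ai[as.integer(rownames(A))] <- A / 3  # barycentric cell area
  if (any(Ai <= 0)) abort_geometry("zero one-ring area during implicit curvature flow")
  K <- Matrix::Diagonal(x = 1 / (4 * Ai)) %*%
    (W - Matrix::Diagonal(x = rs))
  M <- Matrix::Diagonal(topo$nv) - config$lambda * config$dt * K
  pn <- tryCatch(as.matrix(Matrix::solve(M, p)),
                 error = function(e) abort_numerical(sprintf(
                   "implicit curvature-flow system unsolvable at iteration %d: %s",
                   it, conditionMessage(e))))
  list(p = pn, state = state)
}

triangle_areas_from <- function(p, faces) {
  a <- p[faces[, 1L], , drop = FALSE]
  u <- p[faces[, 2L], , drop = FALSE] - a
  w <- p[faces[, 3L], , drop = FALSE] - a
  crs <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
               u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
               u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  0.5 * sqrt(rowSums(crs^2))
}

#' Laplacian smoothing with pre-dilation
#'
#' Dilates the mesh by `dilation_fraction` (+5\% volume by default), then
#' applies uniform Laplacian iterations until either (a) the smoothed volume
#' is back within `volume_threshold` of the original volume, (b) any vertex
#' of the current iterate falls strictly inside the original (pre-dilation)
#' surface, detected by a generalized winding-number query against the
#' original mesh, or (c) the iteration cap `max_iterations` is hit, which is
#' reported as non-convergence. Called by [smooth_mesh()] for method `M2`.
#'
#' @inheritParams smooth_mesh
#' @return a `smooth_result`; `termination$reason` is one of `"threshold"`,
#'   `"contact"`, `"cap"`.
#' @export
smooth_predilated <- function(mesh, config) {
  if (config$method != "M2") abort_usage("smooth_predilated needs method M2")
  v0 <- mesh_volume(mesh)
  if (v0 <= 0) abort_geometry("pre-dilation smoothing needs a positive original volume")
  dil <- dilate_mesh(mesh, config$dilation_fraction)
  topo <- mesh_topology(mesh)
  p <- dil$mesh$vertices
  A <- edge_weight_matrix(topo, rep(1, length(topo$ei)))
  m <- Matrix::rowSums(A)
  vols <- mesh_volume(dil$mesh)
  reason <- "cap"
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    p <- p + config$lambda * (as.matrix(A %*% p) / m - p)
    cur <- mesh; cur$vertices <- p
    vols <- c(vols, mesh_volume(cur))
    if (abs(vols[length(vols)] - v0) <= config$volume_threshold * v0) {
      reason <- "threshold"
      break
    }
    wn <- cpp_winding_number(p, mesh$vertices, mesh$faces)
    if (any(wn > 0.5)) {
      reason <- "contact"
      break
    }
  }
  out <- mesh
  out$vertices <- p
  smooth_result(out, config, vols, it, reason, alpha = dil$alpha,
                converged = reason != "cap")
}
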