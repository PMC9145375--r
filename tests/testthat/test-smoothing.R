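methods_fixed <- c("M1", "M3", "M4", "M5")

test_that("lambda = 0 leaves every mesh unchanged for all fixed-iteration methods", {
  mesh <- jittered_icosphere(seed = 5)
  for (m in methods_fixed) {
    res <- smooth_mesh(mesh, smooth_config(m, lambda = 0, iterations = 3))
    expect_identical(res$mesh$vertices, mesh$vertices)
    expect_identical(res$mesh$faces, mesh$faces)
  }
})

test_that("one M1 iteration equals the per-vertex umbrella oracle", {
  mesh <- jittered_icosphere(seed = 9)
  lam <- 0.37
  res <- smooth_mesh(mesh, smooth_config("M1", lambda = lam, iterations = 1))
  adj <- build_adjacency(mesh)
  for (i in seq_len(nrow(mesh$vertices))) {
    want <- mesh$vertices[i, ] +
      lam * oracle_umbrella(mesh$vertices[i, ],
                            mesh$vertices[adj$neighbors[[i]], ])
    expect_equal(res$mesh$vertices[i, ], want, tolerance = 1e-12)
  }
})

test_that("M1 volume decreases strictly monotonically on a convex mesh", {
  res <- smooth_mesh(icosphere(2), smooth_config("M1", lambda = 0.5,
                                                 iterations = 30))
  expect_length(res$volume_log, 31L)
  expect_true(all(diff(res$volume_log) < 0))
})

test_that("dilation solves the target volume to 1e-6 and is radial on spheres", {
  ic <- icosphere(2)
  d0 <- dilate_mesh(ic, 0)
  expect_identical(d0$mesh$vertices, ic$vertices)
  expect_identical(d0$alpha, 0)
  d <- dilate_mesh(ic, 0.05)
  expect_equal(mesh_volume(d$mesh) / mesh_volume(ic), 1.05, tolerance = 1e-6)
  radii <- sqrt(rowSums(d$mesh$vertices^2))
  expect_equal(radii, rep(1.05^(1 / 3), length(radii)), tolerance = 0.005)
  # on a stair-step phantom too (post-condition via mesh_volume)
  ph <- generate_phantom("ellipsoid")
  vm <- extract_surface(ph, "voxel")
  dp <- dilate_mesh(vm, 0.05)
  expect_equal(mesh_volume(dp$mesh) / mesh_volume(vm), 1.05, tolerance = 1e-6)
  expect_gt(dp$alpha, 0)
})

test_that("pre-dilation smoothing terminates with a recorded reason and honest volume log", {
  ph <- generate_phantom("ellipsoid")
  mesh <- extract_surface(ph, "voxel")
  cfg <- smooth_config("M2")
  res <- smooth_mesh(mesh, cfg)
  expect_true(res$termination$reason %in% c("threshold", "contact", "cap"))
  v0 <- mesh_volume(mesh)
  if (res$termination$reason == "threshold")
    expect_lte(abs(mesh_volume(res$mesh) - v0), cfg$volume_threshold * v0)
  # volume log matches a standalone decomposition: dilate once, then repeated
  # single M1 steps on the running mesh
  dil <- dilate_mesh(mesh, cfg$dilation_fraction)
  cur <- dil$mesh
  expect_equal(res$volume_log[1L], mesh_volume(cur), tolerance = 1e-12)
  for (it in seq_len(res$iterations_run)) {
    step <- smooth_mesh(cur, smooth_config("M1", lambda = cfg$lambda,
                                           iterations = 1))
    cur <- step$mesh
    expect_equal(res$volume_log[it + 1L], mesh_volume(cur), tolerance = 1e-12)
  }
  expect_equal(res$mesh$vertices, cur$vertices, tolerance = 1e-12)
})

test_that("pre-dilation smoothing with lambda = 0 stops only at the iteration cap", {
  ph <- generate_phantom("ellipsoid")
  mesh <- extract_surface(ph, "voxel")
  res <- smooth_mesh(mesh, smooth_config("M2", lambda = 0,
                                         max_iterations = 25))
  expect_identical(res$termination$reason, "cap")
  expect_false(res$termination$converged)
  expect_identical(res$iterations_run, 25L)
})

test_that("M5 equals M1 and M3 is parallel to M1 on the uniform-edge icosahedron", {
  ih <- icosahedron()
  p1 <- smooth_mesh(ih, smooth_config("M1", iterations = 1))$mesh$vertices
  p5 <- smooth_mesh(ih, smooth_config("M5", iterations = 1))$mesh$vertices
  expect_equal(p5, p1, tolerance = 1e-12)
  p3 <- smooth_mesh(ih, smooth_config("M3", iterations = 1))$mesh$vertices
  d1 <- p1 - ih$vertices
  d3 <- p3 - ih$vertices
  for (i in seq_len(nrow(d1))) {
    cr <- c(d1[i, 2] * d3[i, 3] - d1[i, 3] * d3[i, 2],
            d1[i, 3] * d3[i, 1] - d1[i, 1] * d3[i, 3],
            d1[i, 1] * d3[i, 2] - d1[i, 2] * d3[i, 1])
    expect_lt(sqrt(sum(cr^2)), 1e-12)
    expect_gte(sum(d1[i, ] * d3[i, ]), 0)  # same direction
  }
})

test_that("M3 shrinks less than M1 on a stair-step phantom at equal settings", {
  ph <- generate_phantom("ellipsoid")
  mesh <- extract_surface(ph, "voxel")
  r1 <- smooth_mesh(mesh, smooth_config("M1"))
  r3 <- smooth_mesh(mesh, smooth_config("M3"))
  rvd1 <- relative_volume_difference(mesh, r1$mesh)$rvd
  rvd3 <- relative_volume_difference(mesh, r3$mesh)$rvd
  expect_lt(abs(rvd3), abs(rvd1))
  r5 <- smooth_mesh(mesh, smooth_config("M5"))
  rvd5 <- relative_volume_difference(mesh, r5$mesh)$rvd
  expect_lt(abs(rvd5), abs(rvd1))
})

test_that("explicit curvature flow shrinks an icosphere self-similarly", {
  res <- smooth_mesh(icosphere(3), smooth_config("M4", lambda = 0.05,
                                                 iterations = 30))
  radii <- sqrt(rowSums(res$mesh$vertices^2))
  expect_lt(max(radii) / min(radii), 1.01)
  expect_lt(mean(radii), 1)  # radius decreases under the flow
})

test_that("implicit curvature flow approaches the identity as dt -> 0", {
  mesh <- jittered_icosphere(seed = 4)
  res <- smooth_mesh(mesh, smooth_config("M4", curvature_mode = "implicit",
                                         dt = 1e-8, iterations = 1))
  bb <- max(apply(mesh$vertices, 2, function(x) diff(range(x))))
  expect_lt(max(abs(res$mesh$vertices - mesh$vertices)), 1e-6 * bb)
})

test_that("all smoothers preserve topology and are bit-reproducible", {
  ph <- generate_phantom("ellipsoid", spacing = c(1, 1, 2))
  mesh <- extract_surface(ph, "voxel")
  for (m in c(methods_fixed, "M2")) {
    cfg <- smooth_config(m, iterations = 5)
    a <- smooth_mesh(mesh, cfg)
    b <- smooth_mesh(mesh, cfg)
    expect_identical(a$mesh$faces, mesh$faces)
    expect_identical(a$mesh$vertices, b$mesh$vertices)  # bit-identical
    expect_identical(a$termination$reason, b$termination$reason)
  }
})

test_that("vertices with zero operator displacement are fixed points", {
  # a flat-capped box: vertices in the middle of a flat face have planar
  # one-rings; under M4 (cotangent) their displacement is exactly zero
  ph <- generate_phantom("superellipsoid",
                         params = list(semi_axes = c(6, 6, 4), exponent = 8))
  mesh <- extract_surface(ph, "voxel")
  topo <- meshfair:::mesh_topology(mesh)
  adj <- build_adjacency(mesh)
  disp4 <- sapply(seq_len(nrow(mesh$vertices)), function(i) {
    q <- mesh$vertices[adj$neighbors[[i]], , drop = FALSE]
    k <- cotangent_curvature_normal(mesh$vertices[i, ], q)
    sqrt(sum(k^2))
  })
  flat <- which(disp4 < 1e-10)
  expect_gt(length(flat), 0L)
  res <- smooth_mesh(mesh, smooth_config("M4", iterations = 1))
  moved <- sqrt(rowSums((res$mesh$vertices - mesh$vertices)^2))
  expect_lt(max(moved[flat]), 1e-9)
})

test_that("configuration invariants are enforced", {
  expect_error(smooth_config("M1", lambda = 1.5), "lambda",
               class = "meshfair_usage_error")
  expect_error(smooth_config("M1", iterations = 0), "iterations",
               class = "meshfair_usage_error")
  expect_error(smooth_config("M2", volume_threshold = 0.1,
                             dilation_fraction = 0.05),
               "smaller", class = "meshfair_usage_error")
  expect_error(smooth_config("M1", dt = -1), "dt",
               class = "meshfair_usage_error")
  expect_identical(smooth_config("scaledep")$method, "M3")
})
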