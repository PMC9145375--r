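test_that("RVD follows its defining identity and perfect-case zero", {
  mesh <- jittered_icosphere(seed = 1)
  expect_identical(relative_volume_difference(mesh, mesh)$rvd, 0)
  # direct substitutions: scale volumes by known factors
  g <- cube_mesh(size = c(10, 5, 2))            # V = 100
  s90 <- cube_mesh(size = c(9, 5, 2))           # V = 90
  expect_equal(relative_volume_difference(g, s90)$rvd, -10)
  s1005 <- cube_mesh(size = c(10.05, 5, 2))     # V = 100.5
  expect_equal(relative_volume_difference(g, s1005)$rvd, 0.5)
  r <- relative_volume_difference(g, s90)
  expect_equal(r$rvd, (r$volume_smoothed - r$volume_ground) /
                 r$volume_ground * 100)
})

test_that("Hausdorff distance: identity zero, concentric spheres, exhaustive oracle", {
  mesh <- jittered_icosphere(seed = 2)
  h0 <- hausdorff_distance(mesh, mesh)
  expect_identical(h0$hausdorff, 0)
  expect_true(all(h0$field_ground == 0) && all(h0$field_smoothed == 0))

  h <- hausdorff_distance(icosphere(3, radius = 1), icosphere(3, radius = 1.2))
  # analytic distance between concentric spheres is 0.2; discretization can
  # only shrink the chordal inner sphere, bound measured via dense sampling
  ic <- icosphere(3)
  chord_defect <- 1 - min(sqrt(rowSums(((ic$vertices[ic$faces[, 1], ] +
    ic$vertices[ic$faces[, 2], ] + ic$vertices[ic$faces[, 3], ]) / 3)^2)))
  expect_equal(h$hausdorff, 0.2, tolerance = chord_defect / 0.2 + 0.01)

  a <- jittered_icosphere(seed = 31, subdivisions = 1)
  b <- translate_mesh(jittered_icosphere(seed = 32, subdivisions = 1),
                      c(0.3, -0.1, 0.2))
  h <- hausdorff_distance(a, b)
  expect_equal(h$field_ground, oracle_point_mesh(a$vertices, b),
               tolerance = 1e-9)
  expect_equal(h$field_smoothed, oracle_point_mesh(b$vertices, a),
               tolerance = 1e-9)
  expect_identical(h$hausdorff, max(h$directed_ground_to_smoothed,
                                    h$directed_smoothed_to_ground))
})

test_that("Hausdorff distance is symmetric, triangle-bounded and translation-Lipschitz", {
  set.seed(77)
  meshes <- lapply(1:3, function(s)
    translate_mesh(jittered_icosphere(seed = 40 + s, subdivisions = 1),
                   runif(3, -0.5, 0.5)))
  hab <- hausdorff_distance(meshes[[1]], meshes[[2]])
  hba <- hausdorff_distance(meshes[[2]], meshes[[1]])
  expect_identical(hab$hausdorff, hba$hausdorff)
  hbc <- hausdorff_distance(meshes[[2]], meshes[[3]])
  hac <- hausdorff_distance(meshes[[1]], meshes[[3]])
  expect_lte(hac$hausdorff, hab$hausdorff + hbc$hausdorff + 1e-12)
  for (s in 1:5) {
    t <- runif(3, -0.4, 0.4)
    ht <- hausdorff_distance(meshes[[1]], translate_mesh(meshes[[2]], t))
    expect_lte(abs(ht$hausdorff - hab$hausdorff), sqrt(sum(t^2)) + 1e-12)
  }
})

test_that("RVD signs encode dilation vs shrinkage", {
  mesh <- icosphere(2)
  dil <- dilate_mesh(mesh, 0.05)$mesh
  expect_gt(relative_volume_difference(mesh, dil)$rvd, 0)
  shr <- smooth_mesh(mesh, smooth_config("M1"))$mesh
  expect_lt(relative_volume_difference(mesh, shr)$rvd, 0)
})

test_that("distance statistics match hand arithmetic and a two-pass oracle", {
  z <- distance_statistics(c(0, 0, 0))
  expect_equal(unname(z), c(0, 0, 0, 0))
  s <- distance_statistics(c(3, 4))
  expect_equal(s[["mean"]], 3.5)
  expect_equal(s[["rms"]], sqrt(12.5))
  expect_equal(s[["max"]], 4)
  expect_equal(s[["sd"]], 0.5)  # population SD
  set.seed(99)
  field <- runif(1000, 0, 3)
  got <- distance_statistics(field)
  m <- 0; for (x in field) m <- m + x; m <- m / length(field)
  v <- 0; q <- 0
  for (x in field) { v <- v + (x - m)^2; q <- q + x^2 }
  expect_equal(got[["mean"]], m, tolerance = 1e-12)
  expect_equal(got[["sd"]], sqrt(v / length(field)), tolerance = 1e-12)
  expect_equal(got[["rms"]], sqrt(q / length(field)), tolerance = 1e-12)
  expect_equal(got[["max"]], max(field))
  expect_gte(got[["rms"]], got[["mean"]])
})

test_that("heat-map export round-trips fields through PLY and CSV", {
  mesh <- icosphere(1)
  tmp <- withr::local_tempdir()
  ply <- file.path(tmp, "zero.ply")
  export_heatmap(mesh, rep(0, nrow(mesh$vertices)), ply)
  back <- read_mesh(ply)
  expect_equal(attr(back, "scalar"), rep(0, nrow(mesh$vertices)))

  field <- seq_len(nrow(mesh$vertices)) * 0.1
  ply2 <- file.path(tmp, "ramp.ply")
  out <- export_heatmap(mesh, field, ply2)
  back2 <- read_mesh(ply2)
  expect_equal(attr(back2, "scalar"), field, tolerance = 1e-15)
  csv <- utils::read.csv(out$csv)
  expect_equal(csv$distance, field)

  h <- hausdorff_distance(mesh, mesh)
  ply3 <- file.path(tmp, "self.ply")
  export_heatmap(mesh, h$field_ground, ply3)
  expect_true(all(attr(read_mesh(ply3), "scalar") == 0))

  expect_error(export_heatmap(mesh, c(1, 2), ply), "length",
               class = "meshfair_usage_error")
})
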