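test_that("adjacency of a tetrahedron is the complete graph", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  tet <- triangle_mesh(v, f)
  adj <- build_adjacency(tet)
  expect_equal(adj$degree, rep(3L, 4))
  for (i in 1:4)
    expect_setequal(adj$neighbors[[i]], setdiff(1:4, i))
})

test_that("every edge of a triangulated cube is shared by exactly two faces", {
  cb <- cube_mesh()
  de <- meshfair:::directed_edges(cb$faces)
  key <- meshfair:::undirected_edge_key(de, nrow(cb$vertices))
  expect_true(all(table(key) == 2))
  expect_silent(validate_mesh(cb))
})

test_that("adjacency equals a brute-force per-vertex scan over faces", {
  mesh <- jittered_icosphere(seed = 7)
  adj <- build_adjacency(mesh)
  f <- mesh$faces
  for (i in seq_len(nrow(mesh$vertices))) {
    inc <- f[rowSums(f == i) > 0, , drop = FALSE]
    expect_setequal(adj$neighbors[[i]], setdiff(unique(as.vector(inc)), i))
  }
  # opposite angles: for each neighbor, the two third vertices of the faces
  # containing the edge give the angles, independently of fan order
  i <- 5L
  for (s in seq_along(adj$neighbors[[i]])) {
    j <- adj$neighbors[[i]][s]
    shared <- f[rowSums(f == i) > 0 & rowSums(f == j) > 0, , drop = FALSE]
    expect_identical(nrow(shared), 2L)
    thirds <- setdiff(as.vector(shared), c(i, j))
    angs <- vapply(thirds, function(k) {
      u <- mesh$vertices[i, ] - mesh$vertices[k, ]
      w <- mesh$vertices[j, ] - mesh$vertices[k, ]
      acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2)))
    }, 0)
    expect_equal(sort(c(adj$alpha[[i]][s], adj$beta[[i]][s])), sort(angs),
                 tolerance = 1e-9)
  }
  # edge lengths symmetric
  for (i in c(1L, 20L)) {
    for (s in seq_along(adj$neighbors[[i]])) {
      j <- adj$neighbors[[i]][s]
      back <- match(i, adj$neighbors[[j]])
      expect_equal(adj$edge_lengths[[i]][s], adj$edge_lengths[[j]][back])
    }
  }
})

test_that("adjacency construction is deterministic", {
  mesh <- jittered_icosphere(seed = 3)
  expect_identical(build_adjacency(mesh), build_adjacency(mesh))
})

test_that("adjacency rejects open and non-manifold meshes", {
  cb <- cube_mesh()
  open_mesh <- cb
  open_mesh$faces <- cb$faces[-1, ]
  expect_error(build_adjacency(open_mesh), "boundary",
               class = "meshfair_topology_error")
  nm <- cb
  nm$faces <- rbind(cb$faces, cb$faces[1, c(1, 3, 2)])
  expect_error(build_adjacency(nm), "non-manifold|orientation",
               class = "meshfair_topology_error")
})

test_that("vertex normals are radial on an icosphere and negate under flips", {
  ic <- icosphere(3)
  n <- vertex_normals(ic)
  radial <- ic$vertices / sqrt(rowSums(ic$vertices^2))
  ang <- acos(pmin(1, rowSums(n * radial)))
  expect_lt(max(ang), 1 * pi / 180)
  flipped <- flip_orientation(ic)
  expect_equal(vertex_normals(flipped), -n)
})

test_that("cube corner normals point along the diagonal", {
  cb <- cube_mesh()
  n <- vertex_normals(cb)
  diag_dir <- sign(cb$vertices) / sqrt(3)
  expect_true(all(rowSums(n * diag_dir) > 0.9))
})

test_that("signed volume: cube exact, orientation antisymmetric, sphere near 4*pi/3", {
  cb <- cube_mesh()
  expect_identical(mesh_volume(cb), 1)
  expect_identical(mesh_volume(flip_orientation(cb)), -1)
  vox <- oracle_sphere_voxel_volume(h = 0.02)
  expect_equal(vox, 4 * pi / 3, tolerance = 0.002)  # oracle sanity
  ic <- icosphere(3)
  expect_equal(mesh_volume(ic), vox, tolerance = 0.02)
})

test_that("volume is translation-invariant and scales cubically", {
  mesh <- jittered_icosphere(seed = 11)
  v0 <- mesh_volume(mesh)
  expect_equal(mesh_volume(translate_mesh(mesh, c(5, -3, 11))), v0,
               tolerance = 1e-9)
  expect_equal(mesh_volume(scale_mesh(mesh, 2.5)), v0 * 2.5^3,
               tolerance = 1e-9)
})

test_that("face normal-area vectors of a closed mesh sum to zero", {
  mesh <- jittered_icosphere(seed = 2)
  cr <- meshfair:::face_cross(mesh)  # magnitude 2x area
  total_area <- sum(sqrt(rowSums(cr^2))) / 2
  expect_lt(max(abs(colSums(cr / 2))), 1e-9 * total_area)
})

test_that("degenerate and invalid meshes are rejected with repair hints", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f_dup <- rbind(c(1, 1, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  expect_error(triangle_mesh(v, f_dup), "degenerate",
               class = "meshfair_topology_error")
  # sliver: two coincident vertices produce a zero-area face
  v_sliver <- rbind(v, c(0, 0, 1))
  f_sliver <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 5),
                    c(1, 5, 3), c(3, 5, 4))
  expect_error(triangle_mesh(v_sliver, f_sliver), "area|repair|edge")
})
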