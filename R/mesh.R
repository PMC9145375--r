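#' Closed triangle surface mesh
#'
#' Constructs a `triangle_mesh`: vertex positions in millimetres plus a face
#' list of vertex-index triples, counter-clockwise when viewed from outside.
#' All smoothing algorithms and metrics in this package operate on this
#' object. Input meshes are expected to be closed and 2-manifold (every edge
#' shared by exactly two faces, traversed in opposite directions), with no
#' topologically degenerate faces (repeated vertex indices) and no
#' geometrically degenerate faces (area below `1e-12` mm^2, which destabilize
#' cotangent weights).
#'
#' @param vertices numeric matrix, n x 3, vertex positions in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param validate logical; run the full structural validation (default TRUE).
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) abort_geometry("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) abort_geometry("faces must be an m x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @method print triangle_mesh
#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  vol <- tryCatch(mesh_volume(x), error = function(e) NA_real_)
  if (is.finite(vol)) cat(sprintf("  signed volume: %.6g mm^3\n", vol))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bounding box: [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Directed edges of all faces: rows (a,b), (b,c), (c,a) per face.
directed_edges <- function(faces) {
  cbind(as.vector(t(faces)),
        as.vector(t(faces[, c(2L, 3L, 1L), drop = FALSE])))
}

# One integer key per undirected edge (i<j), vectorized.
undirected_edge_key <- function(edges, nv) {
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  (as.double(lo) - 1) * nv + as.double(hi)
}

#' Validate the structural invariants of a triangle mesh
#'
#' Checks index ranges, topologically and geometrically degenerate faces,
#' closedness (every edge incident to exactly two faces), consistent outward
#' orientation (each shared edge traversed in opposite directions), and a
#' strictly positive signed volume.
#'
#' @param mesh a `triangle_mesh`.
#' @param require_positive_volume logical; also require signed volume > 0.
#' @return `mesh`, invisibly; errors describe the offending edges otherwise.
#' @export
validate_mesh <- function(mesh, require_positive_volume = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  if (nv < 4L || nrow(f) < 4L)
    abort_geometry("a closed triangle mesh needs at least 4 vertices and 4 faces")
  if (anyNA(v) || any(!is.finite(v)))
    abort_geometry("non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nv)
    abort_topology("face index out of range: faces must reference existing vertices")
  dup <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
  if (any(dup))
    abort_topology(sprintf("%d topologically degenerate face(s) repeat a vertex (first: face %d)",
                           sum(dup), which(dup)[1L]))
  areas <- face_areas(mesh)
  if (any(areas < 1e-12))
    abort_geometry(sprintf(
      "%d geometrically degenerate face(s) with area < 1e-12 mm^2 (first: face %d); repair (e.g. weld or remove slivers) before smoothing",
      sum(areas < 1e-12), which(areas < 1e-12)[1L]))
  de <- directed_edges(f)
  key <- undirected_edge_key(de, nv)
  cnt <- table(key)
  bad <- cnt != 2L
  if (any(bad)) {
    k <- as.double(names(cnt)[bad][1L])
    i <- floor((k - 1) / nv) + 1
    j <- k - (i - 1) * nv
    n1 <- sum(cnt == 1L)
    nm <- sum(cnt > 2L)
    if (nm > 0L)
      abort_topology(sprintf("non-manifold mesh: %d edge(s) shared by more than 2 faces (e.g. edge %d-%d)",
                             nm, i, j))
    abort_topology(sprintf("open mesh: %d boundary edge(s) with a single incident face (e.g. edge %d-%d); closed meshes only",
                           n1, i, j))
  }
  # opposite traversal: each directed edge must occur exactly once
  dkey <- (as.double(de[, 1L]) - 1) * nv + as.double(de[, 2L])
  if (anyDuplicated(dkey))
    abort_topology("inconsistent orientation: some edge is traversed in the same direction by both incident faces")
  if (require_positive_volume && mesh_volume(mesh) <= 0)
    abort_geometry("signed volume is not positive; mesh orientation is inward or geometry is degenerate")
  invisible(mesh)
}

# Cross products (b-a) x (c-a) per face; |.| = 2 x face area.
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  u <- v[f[, 2L], , drop = FALSE] - a
  w <- v[f[, 3L], , drop = FALSE] - a
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

#' Face areas of a triangle mesh
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area
#' @param mesh a `triangle_mesh`.
#' @return total area (mm^2).
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Signed enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem volume: \eqn{V = \frac{1}{6}\sum_f \det(a_f, b_f, c_f)}
#' over the face vertex triples. Positive for outward orientation; exact for
#' polyhedra and independent of any voxel resolution.
#'
#' @param mesh a `triangle_mesh`.
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
          a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
          a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  sum(det3) / 6
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident face normals (the sum of un-normalized
#' face cross products, which carry area weight intrinsically), normalized to
#' unit length. Robust on irregular stair-step meshes.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric matrix n x 3 of unit normals.
#' @export
vertex_normals <- function(mesh) {
  f <- mesh$faces
  cr <- face_cross(mesh)
  idx <- as.vector(f)  # corners stacked column-wise, aligned with rbind below
  acc <- rowsum(rbind(cr, cr, cr), group = idx, reorder = FALSE)
  ord <- as.integer(rownames(acc))
  n <- matrix(0, nrow(mesh$vertices), 3L)
  n[ord, ] <- acc
  len <- sqrt(rowSums(n^2))
  if (any(len < 1e-300))
    abort_geometry("zero-length vertex normal: all incident faces degenerate")
  n / len
}

#' Axis-aligned box mesh
#'
#' A rectangular box triangulated into 12 outward-oriented faces. Useful as a
#' fixture with known exact volume.
#'
#' @param size numeric length-3 (or scalar) edge lengths in mm.
#' @param center numeric length-3 box center.
#' @return a `triangle_mesh`.
#' @export
cube_mesh <- function(size = 1, center = c(0, 0, 0)) {
  size <- rep_len(as.numeric(size), 3L)
  h <- size / 2
  corners <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                                   z = c(-h[3], h[3])))
  corners <- sweep(corners, 2L, as.numeric(center), "+")
  # corner index = 1 + x + 2y + 4z (bits); quads per axis-aligned side,
  # wound counter-clockwise seen from outside
  quads <- rbind(
    c(1L, 5L, 7L, 3L),  # x = -h
    c(2L, 4L, 8L, 6L),  # x = +h
    c(1L, 2L, 6L, 5L),  # y = -h
    c(3L, 7L, 8L, 4L),  # y = +h
    c(1L, 3L, 4L, 2L),  # z = -h
    c(5L, 6L, 8L, 7L))  # z = +h
  faces <- do.call(rbind, lapply(seq_len(nrow(quads)), function(q) {
    rbind(quads[q, c(1L, 2L, 3L)], quads[q, c(1L, 3L, 4L)])
  }))
  triangle_mesh(corners, faces)
}

#' Regular icosahedron mesh
#'
#' All 30 edges have equal length; handy for checking uniform-edge limit
#' equivalences between smoothers.
#'
#' @param radius circumscribed sphere radius (mm).
#' @return a `triangle_mesh` with 12 vertices and 20 faces.
#' @export
icosahedron <- function(radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2) * radius
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(v, f)
}

#' Icosphere mesh
#'
#' Loop-subdivided icosahedron with vertices projected back to the sphere.
#'
#' @param subdivisions integer number of 4-to-1 subdivision rounds.
#' @param radius sphere radius (mm).
#' @param center sphere center.
#' @return a `triangle_mesh`.
#' @export
icosphere <- function(subdivisions = 2, radius = 1, center = c(0, 0, 0)) {
  mesh <- icosahedron(1)
  v <- mesh$vertices
  f <- mesh$faces
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    de <- directed_edges(f)
    key <- undirected_edge_key(de, nv)
    ukey <- unique(key)
    midindex <- match(key, ukey) + nv
    lo <- floor((ukey - 1) / nv) + 1
    hi <- ukey - (lo - 1) * nv
    mids <- (v[lo, , drop = FALSE] + v[hi, , drop = FALSE]) / 2
    v <- rbind(v, mids)
    m_ab <- midindex[seq(1L, length(key), by = 3L)]
    m_bc <- midindex[seq(2L, length(key), by = 3L)]
    m_ca <- midindex[seq(3L, length(key), by = 3L)]
    f <- rbind(cbind(f[, 1L], m_ab, m_ca),
               cbind(f[, 2L], m_bc, m_ab),
               cbind(f[, 3L], m_ca, m_bc),
               cbind(m_ab,    m_bc, m_ca))
    v <- v / sqrt(rowSums(v^2))
  }
  v <- v * radius
  v <- sweep(v, 2L, as.numeric(center), "+")
  triangle_mesh(v, f)
}

#' Translate, scale or flip a mesh
#'
#' Small conveniences used by tests and examples.
#'
#' @param mesh a `triangle_mesh`.
#' @param offset length-3 translation (mm).
#' @name mesh-transforms
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2L, as.numeric(offset), "+")
  mesh
}

#' @rdname mesh-transforms
#' @param s scalar scale factor.
#' @export
scale_mesh <- function(mesh, s) {
  mesh$vertices <- mesh$vertices * s
  mesh
}

#' @rdname mesh-transforms
#' @export
flip_orientation <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}
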