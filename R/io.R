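#' Read a surface mesh file
#'
#' Supported formats: STL (ASCII and binary), PLY (ASCII and binary little
#' endian, with an optional per-vertex scalar carried in a `quality`
#' property), OBJ. Coordinates are taken to be millimetres. On load,
#' duplicate vertices within 1e-9 mm are welded (STL stores every facet's
#' corners independently), the structural invariants of a closed manifold
#' mesh are validated, and orientation is fixed to outward (positive signed
#' volume) with the flip recorded.
#'
#' @param path file path; format recognized from the extension (`.stl`,
#'   `.ply`, `.obj`) or content sniffing.
#' @param format optional explicit format override.
#' @return a `triangle_mesh` with attributes `orientation_flipped` (logical),
#'   `welded_duplicates` (count of merged duplicate vertices) and, for PLY
#'   with a quality property, `scalar` (numeric per-vertex field).
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (is.null(format)) format <- guess_mesh_format(path)
  raw <- switch(format,
                stl = read_stl(path),
                ply = read_ply(path),
                obj = read_obj(path),
                abort_io(sprintf("unrecognized mesh format: %s", format)))
  welded <- weld_vertices(raw$vertices, raw$faces, scalar = raw$scalar)
  mesh <- tryCatch(
    triangle_mesh(welded$vertices, welded$faces, validate = FALSE),
    error = function(e) abort_io(conditionMessage(e)))
  validate_mesh(mesh, require_positive_volume = FALSE)
  flipped <- FALSE
  if (mesh_volume(mesh) < 0) {
    mesh <- flip_orientation(mesh)
    flipped <- TRUE
  }
  validate_mesh(mesh)
  attr(mesh, "orientation_flipped") <- flipped
  attr(mesh, "welded_duplicates") <- welded$duplicates
  if (!is.null(welded$scalar)) attr(mesh, "scalar") <- welded$scalar
  mesh
}

guess_mesh_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("stl", "ply", "obj")) return(ext)
  head <- readBin(path, "raw", 16L)
  if (length(head) >= 3L && rawToChar(head[1:3]) == "ply") return("ply")
  abort_io(sprintf("cannot determine mesh format of %s", path))
}

# Merge duplicate vertices within 1e-9 mm (fixed tolerance: STL duplication
# is exact, and looser welds corrupt sub-voxel stair-step geometry).
weld_vertices <- function(vertices, faces, scalar = NULL, tol = 1e-9) {
  key <- apply(round(vertices / tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  out_v <- vertices[first, , drop = FALSE]
  out_f <- matrix(remap[faces], ncol = 3L)
  out_s <- if (!is.null(scalar)) scalar[first] else NULL
  list(vertices = out_v, faces = out_f, scalar = out_s,
       duplicates = nrow(vertices) - nrow(out_v))
}

#' Write a surface mesh file
#'
#' @param mesh a valid `triangle_mesh`.
#' @param path output path.
#' @param format `"stl"`, `"ply"` or `"obj"`; default from the extension.
#' @param binary write binary STL / binary little-endian PLY (default FALSE:
#'   ASCII with full double precision). OBJ is always ASCII.
#' @param scalar optional per-vertex numeric field; only PLY can carry it (in
#'   a `quality` property) - STL and OBJ refuse it with an error.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE,
                       scalar = NULL) {
  if (is.null(format)) format <- tolower(sub(".*\\.", "", path))
  if (!format %in% c("stl", "ply", "obj"))
    abort_usage(sprintf("unsupported mesh format: %s", format))
  if (!is.null(scalar)) {
    if (format != "ply")
      abort_usage(sprintf("per-vertex scalars are only supported by PLY, not %s",
                          toupper(format)))
    if (length(scalar) != nrow(mesh$vertices))
      abort_usage("scalar length must match vertex count")
  }
  switch(format,
         stl = write_stl(mesh, path, binary),
         ply = write_ply(mesh, path, binary, scalar),
         obj = write_obj(mesh, path))
  invisible(path)
}

## ---- STL ----

is_binary_stl <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  !is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.double(ntri)
}

read_stl <- function(path) {
  if (is_binary_stl(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rec <- readBin(con, "raw", 50L * ntri)
    m <- matrix(rec, nrow = 50L)
    vals <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                    n = 12L * ntri, endian = "little")
    vals <- matrix(vals, ncol = 12L, byrow = TRUE)
    verts <- rbind(vals[, 4:6, drop = FALSE], vals[, 7:9, drop = FALSE],
                   vals[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
    verts <- verts[ord, , drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      abort_io("malformed ASCII STL: vertex count not a multiple of 3")
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  }
  if (anyNA(verts)) abort_io("malformed STL: non-numeric vertex data")
  ntri <- nrow(verts) / 3L
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces, scalar = NULL)
}

write_stl <- function(mesh, path, binary) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  nrm <- cr / pmax(sqrt(rowSums(cr^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    block <- cbind(nrm, v[f[, 1L], ], v[f[, 2L], ], v[f[, 3L], ])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt3 <- function(x) paste(sprintf("%.17g", x), collapse = " ")
    out <- character(2L + 7L * nrow(f))
    out[1L] <- "solid mesh"
    pos <- 2L
    for (i in seq_len(nrow(f))) {
      out[pos:(pos + 6L)] <- c(
        paste("facet normal", fmt3(nrm[i, ])),
        "  outer loop",
        paste("    vertex", fmt3(v[f[i, 1L], ])),
        paste("    vertex", fmt3(v[f[i, 2L], ])),
        paste("    vertex", fmt3(v[f[i, 3L], ])),
        "  endloop",
        "endfacet")
      pos <- pos + 7L
    }
    out[pos] <- "endsolid mesh"
    writeLines(out, path)
  }
  invisible(path)
}

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- read_line_binary(con)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000L) abort_io("malformed PLY: no end_header")
  }
  if (!grepl("^ply", header[1L])) abort_io("not a PLY file")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) abort_io("malformed PLY header: missing format")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    abort_io(sprintf("unsupported PLY format: %s", fmt))

  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], list = TRUE, count_type = tok[3L],
               value_type = tok[4L])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], list = FALSE, value_type = tok[2L])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    abort_io("PLY file lacks vertex or face elements")

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    out <- parse_ply_ascii(body, elements)
  } else {
    out <- parse_ply_binary(con, elements)
  }
  vp <- vapply(elements$vertex$props, function(p) p$name, "")
  need <- match(c("x", "y", "z"), vp)
  if (anyNA(need)) abort_io("PLY vertex element lacks x/y/z")
  verts <- out$vertex[, need, drop = FALSE]
  scalar <- if ("quality" %in% vp) out$vertex[, match("quality", vp)] else NULL
  faces <- out$faces
  if (any(vapply(faces, length, 1L) != 3L))
    abort_io("PLY contains non-triangular faces")
  faces <- do.call(rbind, faces) + 1L
  list(vertices = verts, faces = faces, scalar = scalar)
}

read_line_binary <- function(con) {
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) abort_io("unexpected end of PLY header")
    if (b == as.raw(10L)) break
    chars <- c(chars, b)
  }
  sub("\r$", "", rawToChar(chars))
}

parse_ply_ascii <- function(body, elements) {
  pos <- 1L
  vertex <- NULL; faces <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      block <- body[pos:(pos + el$count - 1L)]
      vertex <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                                      as.numeric))
      pos <- pos + el$count
    } else if (el$name == "face") {
      block <- body[pos:(pos + el$count - 1L)]
      faces <- lapply(strsplit(trimws(block), "\\s+"), function(x) {
        n <- as.integer(x[1L])
        as.integer(x[2:(1L + n)])
      })
      pos <- pos + el$count
    } else {
      pos <- pos + el$count
    }
  }
  list(vertex = vertex, faces = faces)
}

ply_type_size <- function(type) {
  switch(type,
         char = , int8 = , uchar = , uint8 = 1L,
         short = , int16 = , ushort = , uint16 = 2L,
         int = , int32 = , uint = , uint32 = 4L,
         float = , float32 = 4L,
         double = , float64 = 8L,
         abort_io(sprintf("unsupported PLY type: %s", type)))
}

read_ply_value <- function(con, type, n = 1L) {
  size <- ply_type_size(type)
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "numeric", n, size = size, endian = "little")
  else
    readBin(con, "integer", n, size = size, endian = "little",
            signed = !(size <= 2L && grepl("^u", type)))
}

parse_ply_binary <- function(con, elements) {
  vertex <- NULL; faces <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      np <- length(el$props)
      types <- vapply(el$props, function(p) p$value_type, "")
      if (length(unique(types)) == 1L && !any(vapply(el$props, `[[`, TRUE, "list"))) {
        vals <- read_ply_value(con, types[1L], el$count * np)
        vertex <- matrix(vals, ncol = np, byrow = TRUE)
      } else {
        vertex <- matrix(0, el$count, np)
        for (i in seq_len(el$count))
          for (j in seq_len(np))
            vertex[i, j] <- read_ply_value(con, types[j], 1L)
      }
    } else if (el$name == "face") {
      p <- el$props[[1L]]
      if (!p$list) abort_io("PLY face element must be a list property")
      faces <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        n <- read_ply_value(con, p$count_type, 1L)
        faces[[i]] <- read_ply_value(con, p$value_type, n)
      }
    } else if (el$count > 0L) {
      abort_io(sprintf("unsupported extra PLY element: %s", el$name))
    }
  }
  list(vertex = vertex, faces = faces)
}

write_ply <- function(mesh, path, binary, scalar = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              "comment meshfair surface mesh",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              if (!is.null(scalar)) "property double quality",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    vb <- if (is.null(scalar)) v else cbind(v, scalar)
    writeBin(as.numeric(t(vb)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    vb <- if (is.null(scalar)) v else cbind(v, scalar)
    vlines <- apply(vb, 1L, function(x) paste(sprintf("%.17g", x), collapse = " "))
    flines <- apply(f - 1L, 1L, function(x) paste(c(3L, x), collapse = " "))
    writeLines(c(header, vlines, flines), path)
  }
  invisible(path)
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    abort_io("malformed OBJ: no vertices or faces")
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*", "", x[-1L]))
    if (length(idx) != 3L) abort_io("OBJ contains non-triangular faces")
    idx
  })
  list(vertices = verts, faces = do.call(rbind, faces), scalar = NULL)
}

write_obj <- function(mesh, path) {
  vlines <- apply(mesh$vertices, 1L, function(x)
    paste("v", paste(sprintf("%.17g", x), collapse = " ")))
  flines <- apply(mesh$faces, 1L, function(x)
    paste("f", paste(x, collapse = " ")))
  writeLines(c("# meshfair surface mesh", vlines, flines), path)
  invisible(path)
}

## ---- NIfTI masks ----

#' Read a binary or labeled segmentation mask as a voxel phantom
#'
#' Reads a NIfTI volume, selects the nonzero voxels (or one label), attaches
#' the header's voxel spacing, and pads the grid with 2 empty voxels per side
#' if the occupied region touches the border. The result carries no analytic
#' descriptor.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param label optional integer label to select; default: all nonzero.
#' @return a `voxel_phantom` (descriptor `NULL`).
#' @export
read_mask <- function(path, label = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_io(conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) abort_io("mask must be a 3D volume")
  if (any(abs(arr - round(arr)) > 1e-9))
    abort_io("mask voxels must be integer-valued (binary or labeled)")
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort_io("mask header lacks positive voxel spacing")
  occ <- if (is.null(label)) arr != 0 else abs(arr - label) < 0.5
  if (!any(occ)) abort_io("mask contains no selected voxels")
  occ <- pad_if_touching(occ)
  structure(list(occupancy = occ, spacing = as.numeric(spacing),
                 origin = c(0, 0, 0), descriptor = NULL),
            class = "voxel_phantom")
}

pad_if_touching <- function(occ, pad = 2L) {
  n <- dim(occ)
  touches <- any(occ[c(1L, n[1]), , ]) || any(occ[, c(1L, n[2]), ]) ||
    any(occ[, , c(1L, n[3])])
  if (!touches) return(occ)
  out <- array(FALSE, n + 2L * pad)
  out[pad + seq_len(n[1]), pad + seq_len(n[2]), pad + seq_len(n[3])] <- occ
  out
}

#' Write a voxel phantom as a NIfTI mask
#'
#' @param phantom a `voxel_phantom`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(phantom, path) {
  arr <- array(as.integer(phantom$occupancy), dim(phantom$occupancy))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- phantom$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
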