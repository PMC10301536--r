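#' Triangle surface meshes
#'
#' A `vc_mesh` holds an n x 3 vertex matrix (mm) and an m x 3 integer face
#' matrix of 1-based vertex indices (0-based indices in files are converted
#' at the I/O boundary). Most operations require the mesh to be watertight
#' (every undirected edge shared by exactly two faces, once in each
#' direction) and outward-oriented (positive signed volume).
#'
#' @param vertices numeric n x 3 matrix, mm.
#' @param faces integer m x 3 matrix, 1-based indices.
#' @return `vc_mesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) > 0L) {
    if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("trimesh(): face indices out of range")
    }
  }
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("trimesh(): non-finite vertex coordinates")
  }
  structure(list(vertices = vertices, faces = faces), class = "vc_mesh")
}

#' An empty mesh (zero faces, zero volume)
#' @export
empty_mesh <- function() {
  trimesh(matrix(numeric(0), ncol = 3L), matrix(integer(0), ncol = 3L))
}

#' @export
print.vc_mesh <- function(x, ...) {
  cat(sprintf("<mesh> %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$faces) > 0L) {
    v <- tryCatch(mesh_volume(x), error = function(e) NA_real_)
    if (!is.na(v)) cat(sprintf(", volume %.2f mm^3", v))
  }
  cat("\n")
  invisible(x)
}

#' Is a mesh empty?
#' @param mesh `vc_mesh`.
#' @export
mesh_is_empty <- function(mesh) nrow(mesh$faces) == 0L

#' Directed boundary edges of a triangle mesh
#'
#' For a closed orientable surface every undirected edge appears exactly
#' twice, once in each direction; edges failing that are boundary (or
#' non-manifold) edges. Returns a 2-column matrix of the unmatched directed
#' edges (zero rows for a watertight mesh).
#'
#' @param mesh `vc_mesh`.
#' @export
mesh_boundary_edges <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(matrix(integer(0), ncol = 2L))
  he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(he[, 1L], he[, 2L])
  rkey <- paste(he[, 2L], he[, 1L])
  unmatched <- !(rkey %in% key) | duplicated(key) | duplicated(key, fromLast = TRUE)
  he[unmatched, , drop = FALSE]
}

#' Check watertightness
#'
#' @param mesh `vc_mesh`.
#' @return `TRUE` if every directed edge is unique and matched by its
#'   reverse; `FALSE` otherwise.
#' @export
mesh_is_watertight <- function(mesh) {
  nrow(mesh_boundary_edges(mesh)) == 0L
}

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedron (divergence theorem) volume:
#' `V = (1/6) * sum over faces of det[a, b, c]` with `a`, `b`, `c` the face
#' vertices. For an outward-oriented watertight surface the sum is positive
#' and equals the enclosed volume in mm^3.
#'
#' @param mesh `vc_mesh`, watertight and outward-oriented.
#' @param signed if `TRUE`, return the raw signed sum without checks
#'   (internal use, e.g. orientation repair).
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  stopifnot(inherits(mesh, "vc_mesh"))
  if (mesh_is_empty(mesh)) return(0)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
    a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
    a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  vol <- sum(det6) / 6
  if (signed) return(vol)
  nb <- nrow(mesh_boundary_edges(mesh))
  if (nb > 0L) {
    stop(sprintf("mesh_volume(): mesh is not watertight (%d boundary edges)", nb))
  }
  if (vol < 0) {
    stop("mesh_volume(): negative signed volume; mesh is inward-oriented (use mesh_repair_orientation())")
  }
  vol
}

#' Per-face areas (mm^2)
#' @param mesh `vc_mesh`.
#' @export
mesh_face_areas <- function(mesh) {
  if (mesh_is_empty(mesh)) return(numeric(0))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Total surface area (mm^2)
#' @param mesh `vc_mesh`.
#' @export
mesh_surface_area <- function(mesh) sum(mesh_face_areas(mesh))

#' Repair global orientation
#'
#' STL exporters disagree on winding. If the signed volume of a watertight
#' mesh is negative, all faces are flipped (with a warning) so the surface
#' is outward-oriented.
#'
#' @param mesh watertight `vc_mesh`.
#' @export
mesh_repair_orientation <- function(mesh) {
  if (mesh_is_empty(mesh)) return(mesh)
  if (mesh_volume(mesh, signed = TRUE) < 0) {
    warning("mesh was inward-oriented; flipping all faces")
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

#' Apply a rigid transform (or any affine map) to a mesh
#'
#' @param mesh `vc_mesh`.
#' @param rotation 3 x 3 matrix (applied on the right as `v %*% t(R)`).
#' @param translation length-3 vector, mm.
#' @export
mesh_transform <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rotation), 2L, -as.numeric(translation))
  mesh
}

#' Drop vertices not referenced by any face, re-indexing faces
#' @param mesh `vc_mesh`.
#' @export
mesh_compact <- function(mesh) {
  if (mesh_is_empty(mesh)) return(empty_mesh())
  used <- sort(unique(as.vector(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(remap[mesh$faces], ncol = 3L))
}

#' Merge coincident vertices
#'
#' STL stores a triangle soup; vertices closer than `tol` (mm) are merged to
#' restore shared-edge connectivity. Zero-area faces produced by the merge
#' are dropped.
#'
#' @param mesh `vc_mesh`.
#' @param tol merge tolerance in mm (default 1e-6).
#' @export
mesh_merge_vertices <- function(mesh, tol = 1e-6) {
  if (mesh_is_empty(mesh)) return(mesh)
  v <- mesh$vertices
  key <- paste(round(v[, 1L] / tol), round(v[, 2L] / tol), round(v[, 3L] / tol))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(idx[mesh$faces], ncol = 3L)
  degen <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
  mesh_compact(trimesh(newv, f[!degen, , drop = FALSE]))
}

#' Axis-aligned box mesh
#'
#' @param lo,hi length-3 corners (mm), `lo < hi` componentwise.
#' @return watertight, outward-oriented `vc_mesh` with 12 faces.
#' @export
mesh_box <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(all(hi > lo))
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: binary (x fastest); faces wound outward
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6)    # x = hi
  )
  mesh_repair_orientation(trimesh(v, f))
}

#' Icosphere mesh
#'
#' Recursive subdivision of an icosahedron, vertices projected to the
#' sphere; standard watertight sphere approximation.
#'
#' @param radius mm.
#' @param center length-3, mm.
#' @param subdivisions integer >= 0.
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nf <- matrix(integer(0), ncol = 3L)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- vector("list", nrow(f))
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; cc <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[[k]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, newf)
  }
  v <- sweep(v * radius, 2L, -as.numeric(center))
  mesh_repair_orientation(trimesh(v, f))
}
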