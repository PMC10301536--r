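#' Cut a watertight mesh by a plane, capping both pieces
#'
#' Splits the mesh into the piece on the positive side of the plane
#' (`above`) and the piece on the negative side (`below`). Crossing
#' triangles are split along the plane; the planar cross-section is closed
#' with triangulated caps (multiple loops and loops with holes supported),
#' so both pieces are again watertight and their volumes sum to the input
#' volume to machine precision.
#'
#' Vertices within `tol` of the plane are snapped onto it before splitting,
#' which avoids sliver triangles; a vertex exactly on the plane belongs to
#' both pieces.
#'
#' @param mesh watertight, outward-oriented `vc_mesh`.
#' @param plane `vc_plane`.
#' @param tol on-plane snap tolerance in mm (default 1e-9).
#' @return `list(above = vc_mesh, below = vc_mesh)`; a side missed by the
#'   plane is returned as [empty_mesh()].
#' @export
cut_mesh <- function(mesh, plane, tol = 1e-9) {
  stopifnot(inherits(mesh, "vc_mesh"), inherits(plane, "vc_plane"))
  if (mesh_is_empty(mesh)) {
    return(list(above = empty_mesh(), below = empty_mesh()))
  }
  nb <- nrow(mesh_boundary_edges(mesh))
  if (nb > 0L) {
    stop(sprintf("cut_mesh(): input mesh not watertight (%d boundary edges)", nb))
  }

  v <- mesh$vertices
  d <- signed_distance(plane, v)
  snap <- abs(d) <= tol
  if (any(snap)) {
    # project snapped vertices exactly onto the plane
    v[snap, ] <- v[snap, , drop = FALSE] -
      outer(d[snap], plane$normal)
    d[snap] <- 0
  }
  s <- sign(d)

  f <- mesh$faces
  fs <- matrix(s[f], ncol = 3L)
  npos <- rowSums(fs > 0)
  nneg <- rowSums(fs < 0)
  crossing <- npos > 0 & nneg > 0

  above_faces <- f[npos > 0 & nneg == 0, , drop = FALSE]
  below_faces <- f[nneg > 0 & npos == 0, , drop = FALSE]
  coplanar <- f[npos == 0 & nneg == 0, , drop = FALSE]  # fully on the plane
  if (nrow(coplanar) > 0L) {
    # tangential contact: keep coplanar faces with the side that has faces;
    # they contribute zero volume either way
    if (nrow(above_faces) >= nrow(below_faces)) {
      above_faces <- rbind(above_faces, coplanar)
    } else {
      below_faces <- rbind(below_faces, coplanar)
    }
  }

  if (!any(crossing)) {
    # plane misses the interior: one side is the whole mesh
    if (nrow(below_faces) == 0L) {
      return(list(above = trimesh(v, f), below = empty_mesh()))
    }
    if (nrow(above_faces) == 0L) {
      return(list(above = empty_mesh(), below = trimesh(v, f)))
    }
  }

  # split crossing triangles; intersection vertices cached per undirected
  # edge so both incident triangles share the same new vertex
  edge_cache <- new.env(hash = TRUE, parent = emptyenv())
  newv <- list()
  n0 <- nrow(v)
  edge_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    p <- p - (sum(plane$normal * p) - plane$offset) * plane$normal
    newv[[length(newv) + 1L]] <<- p
    id <- n0 + length(newv)
    edge_cache[[key]] <- id
    id
  }

  ab_new <- list(); bl_new <- list()
  for (k in which(crossing)) {
    tri <- f[k, ]
    st <- s[tri]
    # rotate so patterns are canonical, preserving winding
    rot <- function(m) { tri <<- tri[c(2L, 3L, 1L)]; st <<- st[c(2L, 3L, 1L)] }
    if (any(st == 0)) {
      # exactly one zero (two zeros cannot cross): rotate zero to slot 1
      while (st[1L] != 0) rot()
      P <- edge_point(tri[2L], tri[3L])
      if (st[2L] > 0) {
        ab_new[[length(ab_new) + 1L]] <- c(tri[1L], tri[2L], P)
        bl_new[[length(bl_new) + 1L]] <- c(tri[1L], P, tri[3L])
      } else {
        bl_new[[length(bl_new) + 1L]] <- c(tri[1L], tri[2L], P)
        ab_new[[length(ab_new) + 1L]] <- c(tri[1L], P, tri[3L])
      }
    } else if (sum(st > 0) == 1L) {
      while (st[1L] <= 0) rot()  # lone positive at slot 1
      Pab <- edge_point(tri[1L], tri[2L])
      Pca <- edge_point(tri[3L], tri[1L])
      ab_new[[length(ab_new) + 1L]] <- c(tri[1L], Pab, Pca)
      bl_new[[length(bl_new) + 1L]] <- c(Pab, tri[2L], tri[3L])
      bl_new[[length(bl_new) + 1L]] <- c(Pab, tri[3L], Pca)
    } else {
      while (st[1L] >= 0) rot()  # lone negative at slot 1
      Pab <- edge_point(tri[1L], tri[2L])
      Pca <- edge_point(tri[3L], tri[1L])
      bl_new[[length(bl_new) + 1L]] <- c(tri[1L], Pab, Pca)
      ab_new[[length(ab_new) + 1L]] <- c(Pab, tri[2L], tri[3L])
      ab_new[[length(ab_new) + 1L]] <- c(Pab, tri[3L], Pca)
    }
  }

  if (length(newv) > 0L) {
    v <- rbind(v, do.call(rbind, newv))
  }
  above_faces <- rbind(above_faces, do.call(rbind, ab_new))
  below_faces <- rbind(below_faces, do.call(rbind, bl_new))

  if (nrow(below_faces) == 0L) {
    return(list(above = mesh_compact(trimesh(v, above_faces)), below = empty_mesh()))
  }
  if (nrow(above_faces) == 0L) {
    return(list(above = empty_mesh(), below = mesh_compact(trimesh(v, below_faces))))
  }

  # cap: boundary of the open below-surface lies on the plane; reversed
  # boundary loops bound the cap with normal +n (outward for `below`)
  loops <- cap_loops(below_faces)
  if (length(loops) > 0L) {
    cap <- cap_triangles(loops, v, plane)
    v <- cap$vertices
    capf <- cap$faces
  } else {
    capf <- matrix(integer(0), ncol = 3L)  # disjoint components, no cut
  }
  below <- mesh_compact(trimesh(v, rbind(below_faces, capf)))
  above <- mesh_compact(trimesh(v, rbind(above_faces,
                                         capf[, c(1L, 3L, 2L), drop = FALSE])))
  for (side in list(above, below)) {
    nbb <- nrow(mesh_boundary_edges(side))
    if (nbb > 0L) {
      stop(sprintf("cut_mesh(): internal error, cut piece has %d boundary edges", nbb))
    }
  }
  list(above = above, below = below)
}

# boundary directed edges of an open face set, chained into closed loops and
# reversed (so outer loops are CCW seen from the +normal side)
cap_loops <- function(faces) {
  he <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- paste(he[, 1L], he[, 2L])
  rkey <- paste(he[, 2L], he[, 1L])
  b <- he[!(rkey %in% key), , drop = FALSE]
  if (nrow(b) == 0L) return(list())
  # reverse each edge, then chain
  b <- b[, c(2L, 1L), drop = FALSE]
  used <- rep(FALSE, nrow(b))
  loops <- list()
  order_idx <- seq_len(nrow(b))
  edge_from <- split(order_idx, b[, 1L])
  for (e0 in order_idx) {
    if (used[e0]) next
    loop <- b[e0, 1L]
    used[e0] <- TRUE
    cur <- b[e0, 2L]
    guard <- 0L
    while (cur != loop[1L]) {
      loop <- c(loop, cur)
      cand <- edge_from[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) stop("cap_loops(): open boundary chain")
      e <- cand[1L]
      used[e] <- TRUE
      cur <- b[e, 2L]
      guard <- guard + 1L
      if (guard > nrow(b)) stop("cap_loops(): chaining guard tripped")
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

cap_triangles <- function(loops, v, plane) {
  n <- plane$normal
  # in-plane orthonormal basis, (e1, e2, n) right-handed
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(cross3(a, n))
  e2 <- cross3(n, e1)
  get2d <- function(i) c(sum(v[i, ] * e1), sum(v[i, ] * e2))
  tc <- triangulate_cap(loops, get2d)
  faces <- matrix(tc$vert_ids[tc$faces], ncol = 3L)
  if (nrow(tc$extra2d) > 0L) {
    origin <- plane$offset * n
    extra3d <- t(apply(tc$extra2d, 1L, function(q) origin + q[1] * e1 + q[2] * e2))
    base <- nrow(v)
    v <- rbind(v, extra3d)
    # fallback extras were indexed after the local vertex list
    nv_local <- length(tc$vert_ids)
    fix <- tc$faces > nv_local
    faces[fix] <- base + (tc$faces[fix] - nv_local)
  }
  list(faces = faces, vertices = v)
}
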