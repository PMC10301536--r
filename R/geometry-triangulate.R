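# Planar polygon triangulation for cap filling.
#
# Input: a set of closed loops in 2D (outer loops CCW, holes CW, as produced
# by reversing the boundary of the open cut surface). Output: triangles whose
# union covers the region (even-odd), wound CCW, using only the loop
# vertices plus (in the fallback path) one added centroid vertex per group.
#
# Primary path: earcut-style hole bridging + ear clipping. Fallback path:
# a centroid fan, which is volume-exact for any closed loop set (signed
# areas cancel) and keeps every loop edge used exactly once, at the price of
# possible geometric overlap; callers that only need enclosed volume and
# combinatorial watertightness are safe either way.

polygon_signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

point_in_polygon <- function(pt, poly) {
  # even-odd crossing test
  n <- nrow(poly)
  j <- c(2:n, 1L)
  x <- poly[, 1L]; y <- poly[, 2L]
  xj <- x[j]; yj <- y[j]
  straddle <- (y > pt[2]) != (yj > pt[2])
  if (!any(straddle)) return(FALSE)
  xs <- x[straddle] + (pt[2] - y[straddle]) / (yj[straddle] - y[straddle]) *
    (xj[straddle] - x[straddle])
  sum(xs > pt[1]) %% 2L == 1L
}

# strict point-in-triangle (boundary does not count), tolerance relative
point_strictly_in_tri <- function(pt, a, b, cc, eps) {
  d1 <- (pt[1] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (pt[2] - b[2])
  d2 <- (pt[1] - cc[1]) * (b[2] - cc[2]) - (b[1] - cc[1]) * (pt[2] - cc[2])
  d3 <- (pt[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (pt[2] - a[2])
  (d1 > eps & d2 > eps & d3 > eps) | (d1 < -eps & d2 < -eps & d3 < -eps)
}

ear_clip <- function(idx, P, eps_area) {
  tris <- matrix(integer(0), ncol = 3L)
  guard <- 0L
  while (length(idx) > 3L) {
    n <- length(idx)
    clipped <- FALSE
    # pass 1: degenerate (collinear/spike) ears are clipped first; they carry
    # zero area but must be emitted to keep boundary-edge pairing intact
    for (i in seq_len(n)) {
      a <- idx[if (i == 1L) n else i - 1L]
      b <- idx[i]
      cc <- idx[if (i == n) 1L else i + 1L]
      v1 <- P[b, ] - P[a, ]; v2 <- P[cc, ] - P[b, ]
      cr <- v1[1] * v2[2] - v1[2] * v2[1]
      if (abs(cr) <= eps_area) {
        tris <- rbind(tris, c(a, b, cc))
        idx <- idx[-i]
        clipped <- TRUE
        break
      }
    }
    if (clipped) next
    for (i in seq_len(n)) {
      a <- idx[if (i == 1L) n else i - 1L]
      b <- idx[i]
      cc <- idx[if (i == n) 1L else i + 1L]
      v1 <- P[b, ] - P[a, ]; v2 <- P[cc, ] - P[b, ]
      cr <- v1[1] * v2[2] - v1[2] * v2[1]
      if (cr <= eps_area) next  # reflex
      others <- setdiff(idx, c(a, b, cc))
      blocked <- FALSE
      for (o in others) {
        if (point_strictly_in_tri(P[o, ], P[a, ], P[b, ], P[cc, ], eps_area)) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) {
        tris <- rbind(tris, c(a, b, cc))
        idx <- idx[-i]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) stop("ear_clip: no ear found")
    guard <- guard + 1L
    if (guard > 100000L) stop("ear_clip: iteration guard tripped")
  }
  if (length(idx) == 3L) tris <- rbind(tris, idx)
  tris
}

# bridge one hole (CW cycle) into a CCW polygon, earcut style
bridge_hole <- function(poly, hole, P, eps_area) {
  hm <- hole[which.max(P[hole, 1L])]   # hole vertex with max x
  M <- P[hm, ]
  n <- length(poly)
  jn <- c(2:n, 1L)
  best_t <- Inf; best_edge <- NA_integer_
  for (i in seq_len(n)) {
    a <- P[poly[i], ]; b <- P[poly[jn[i]], ]
    if ((a[2] > M[2]) == (b[2] > M[2])) next
    xi <- a[1] + (M[2] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
    if (xi >= M[1] - sqrt(eps_area) && xi < best_t) {
      best_t <- xi
      best_edge <- i
    }
  }
  if (is.na(best_edge)) stop("bridge_hole: no visible edge")
  a_i <- poly[best_edge]; b_i <- poly[jn[best_edge]]
  # candidate bridge vertex: edge endpoint with larger x
  cand <- if (P[a_i, 1L] >= P[b_i, 1L]) best_edge else jn[best_edge]
  Ppt <- c(best_t, M[2])
  # reflex vertices of poly inside triangle (M, I, P_cand) may occlude; pick
  # the one with the smallest angle from +x
  pc <- P[poly[cand], ]
  sel <- cand
  best_ang <- Inf
  for (i in seq_len(n)) {
    q <- P[poly[i], ]
    if (identical(i, cand)) next
    if (point_strictly_in_tri(q, M, Ppt, pc, eps_area) && q[1] >= M[1]) {
      ang <- abs(atan2(q[2] - M[2], q[1] - M[1]))
      if (ang < best_ang) {
        best_ang <- ang
        sel <- i
      }
    }
  }
  # splice: ... P_sel, M, hole cycle..., M, P_sel, ... (bridge edge doubled)
  hstart <- match(hm, hole)
  hcycle <- c(hole[hstart:length(hole)], hole[seq_len(hstart - 1L)])
  c(
    poly[seq_len(sel)], hcycle, hm, poly[sel],
    if (sel < n) poly[(sel + 1L):n] else integer(0)
  )
}

# triangulate a group of loops given as local index cycles into P (2D coords);
# loops[[1]] is the CCW outer, the rest CW holes. Returns local triangles and
# optionally extra 2D points (centroid fan fallback).
triangulate_group <- function(loops, P) {
  diam2 <- max(apply(P, 2L, function(u) diff(range(u)))^2, 1e-30)
  eps_area <- diam2 * 1e-12
  res <- tryCatch({
    poly <- loops[[1L]]
    holes <- loops[-1L]
    if (length(holes) > 0L) {
      ord <- order(vapply(holes, function(h) max(P[h, 1L]), 0), decreasing = TRUE)
      for (h in holes[ord]) poly <- bridge_hole(poly, h, P, eps_area)
    }
    list(tris = ear_clip(poly, P, eps_area), extra = NULL)
  }, error = function(e) NULL)
  if (!is.null(res)) return(res)
  # centroid fan fallback: exact area/volume by signed cancellation
  all_idx <- unlist(loops)
  q <- colMeans(P[all_idx, , drop = FALSE])
  qi <- nrow(P) + 1L
  tris <- do.call(rbind, lapply(loops, function(lp) {
    n <- length(lp)
    cbind(qi, lp, lp[c(2:n, 1L)])
  }))
  list(tris = tris, extra = matrix(q, ncol = 2L))
}

# Full cap triangulation: loops are index cycles into the global vertex set,
# pts2d the matching 2D coordinates (rows aligned with `unlist(loops)` via
# `vert_ids`). Returns list(faces = m x 3 global ids, new_pts2d, new_origin
# handled by caller).
triangulate_cap <- function(loops, get2d) {
  vert_ids <- unique(unlist(loops))
  P <- t(vapply(vert_ids, get2d, numeric(2)))
  local <- function(g) match(g, vert_ids)
  loops_l <- lapply(loops, local)
  areas <- vapply(loops_l, function(lp) polygon_signed_area(P[lp, , drop = FALSE]), 0)
  # nesting depth by even-odd containment of a sample vertex
  nl <- length(loops_l)
  depth <- integer(nl)
  parent <- rep(NA_integer_, nl)
  for (i in seq_len(nl)) {
    best_area <- Inf
    for (j in seq_len(nl)) {
      if (i == j) next
      if (point_in_polygon(P[loops_l[[i]][1L], ], P[loops_l[[j]], , drop = FALSE])) {
        depth[i] <- depth[i] + 1L
        aj <- abs(areas[j])
        if (aj < best_area) {
          best_area <- aj
          parent[i] <- j
        }
      }
    }
  }
  outer <- which(depth %% 2L == 0L)
  faces <- matrix(integer(0), ncol = 3L)
  extra2d <- matrix(numeric(0), ncol = 2L)
  Pwork <- P
  for (o in outer) {
    kids <- which(!is.na(parent) & parent == o & depth %% 2L == 1L)
    grp <- c(list(loops_l[[o]]), loops_l[kids])
    # orientation sanity: outer should be CCW, holes CW (from boundary
    # reversal); if the outer is CW the upstream orientation is broken and
    # the fan fallback still yields the right signed area
    tg <- triangulate_group(grp, Pwork)
    if (!is.null(tg$extra)) {
      Pwork <- rbind(Pwork, tg$extra)
      extra2d <- rbind(extra2d, tg$extra)
    }
    faces <- rbind(faces, tg$tris)
  }
  list(faces = faces, vert_ids = vert_ids, extra2d = extra2d)
}
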