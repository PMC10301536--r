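#' Oriented infinite planes
#'
#' A plane is stored as a unit normal and an offset, so that the plane is
#' the locus `{p : normal . p == offset}` (all lengths in mm). The side the
#' normal points to is semantically meaningful throughout the package: the
#' cephalometric plane stack orients horizontal cut normals superior and the
#' coronal cut normal anterior.
#'
#' @param normal numeric length-3; need not be unit length on input.
#' @param offset numeric scalar, mm.
#' @return An object of class `vc_plane` with fields `normal` (unit 3-vector)
#'   and `offset` (mm).
#' @export
plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3L, is.finite(offset))
  nrm <- sqrt(sum(normal^2))
  if (!is.finite(nrm) || nrm < 1e-12) {
    stop("plane(): normal has (near-)zero length")
  }
  structure(
    list(normal = normal / nrm, offset = as.numeric(offset) / nrm),
    class = "vc_plane"
  )
}

#' @export
print.vc_plane <- function(x, ...) {
  cat(sprintf(
    "<plane> normal = (%.6f, %.6f, %.6f), offset = %.6f mm\n",
    x$normal[1], x$normal[2], x$normal[3], x$offset
  ))
  invisible(x)
}

#' Plane through three points
#'
#' Constructs the unique plane containing three non-collinear points. When
#' `orient_toward` is supplied the normal is flipped, if necessary, so that
#' point has non-negative signed distance.
#'
#' @param p1,p2,p3 numeric length-3 points (mm).
#' @param orient_toward optional numeric length-3 point that should end up on
#'   the non-negative side.
#' @return `vc_plane`.
#' @export
plane_from_points <- function(p1, p2, p3, orient_toward = NULL) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- cross3(p2 - p1, p3 - p1)
  area2 <- sqrt(sum(n^2)) # twice the triangle area
  if (area2 / 2 <= 1e-9) {
    stop(sprintf(
      "degenerate plane: points (%g,%g,%g), (%g,%g,%g), (%g,%g,%g) are collinear",
      p1[1], p1[2], p1[3], p2[1], p2[2], p2[3], p3[1], p3[2], p3[3]
    ))
  }
  pl <- plane(n, sum(n * p1))
  orient_plane(pl, orient_toward)
}

#' Least-squares plane through a point cloud
#'
#' Total-least-squares fit: minimises the sum of squared orthogonal distances
#' (the smallest principal axis of the centred points is the normal). With
#' exactly three points this reduces to [plane_from_points()].
#'
#' @param points numeric matrix, one row per point (n x 3), n >= 3.
#' @inheritParams plane_from_points
#' @return `vc_plane`.
#' @export
plane_fit <- function(points, orient_toward = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L || ncol(points) != 3L) {
    stop("plane_fit(): need an n x 3 matrix with n >= 3")
  }
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x, nu = 0L, nv = 3L)
  # rank check: the two largest singular values must be non-degenerate,
  # otherwise the points are (near-)collinear and the normal is not defined
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1)) {
    stop("plane_fit(): points are collinear or coincident; plane undefined")
  }
  n <- sv$v[, 3L]
  pl <- plane(n, sum(n * ctr))
  orient_plane(pl, orient_toward)
}

#' Signed distance from a plane
#'
#' Positive on the side the plane normal points to, in mm. `p` may be a
#' single point or an n x 3 matrix (returns a vector).
#'
#' @param plane `vc_plane`.
#' @param p numeric length-3 point or n x 3 matrix.
#' @export
signed_distance <- function(plane, p) {
  stopifnot(inherits(plane, "vc_plane"))
  if (is.matrix(p)) {
    as.numeric(p %*% plane$normal) - plane$offset
  } else {
    sum(plane$normal * as.numeric(p)) - plane$offset
  }
}

#' Flip a plane's orientation
#' @param plane `vc_plane`.
#' @export
plane_flip <- function(plane) {
  plane(-plane$normal, -plane$offset)
}

orient_plane <- function(pl, orient_toward) {
  if (is.null(orient_toward)) return(pl)
  if (signed_distance(pl, as.numeric(orient_toward)) < 0) plane_flip(pl) else pl
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}
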