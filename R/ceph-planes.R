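#' Cephalometric landmark sets
#'
#' A landmark set is a named list of 3D points (mm). Required landmarks:
#' both porions, left orbitale, ANS, PNS, one anterior and two molar
#' occlusal points, both gonions, menton, and both mental foramina; the
#' right orbitale is optional and upgrades the Frankfort plane to a
#' four-point least-squares fit. Unknown names are preserved but ignored.
#'
#' @param points named list (or named n x 3 matrix) of 3D points, mm.
#' @return `vc_landmarks`: validated named list of length-3 numeric vectors.
#' @export
landmark_set <- function(points) {
  if (is.matrix(points)) {
    points <- stats::setNames(
      lapply(seq_len(nrow(points)), function(i) as.numeric(points[i, ])),
      rownames(points)
    )
  }
  req <- required_landmarks()
  nm <- names(points)
  if (is.null(nm) || any(nm == "")) stop("landmark_set(): all points must be named")
  if (anyDuplicated(nm)) {
    stop("landmark_set(): duplicate landmark names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  missing <- setdiff(req, nm)
  if (length(missing) > 0L) {
    stop("landmark_set(): missing required landmarks: ",
         paste(missing, collapse = ", "))
  }
  pts <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || any(!is.finite(p))) {
      stop("landmark_set(): every landmark must be 3 finite coordinates (mm)")
    }
    p
  })
  pairs <- list(
    c("porion_l", "porion_r"),
    c("gonion_l", "gonion_r"),
    c("mental_foramen_l", "mental_foramen_r"),
    c("occlusal_molar_l", "occlusal_molar_r")
  )
  for (pr in pairs) {
    gap <- sqrt(sum((pts[[pr[1]]] - pts[[pr[2]]])^2))
    if (gap < 10) {
      stop(sprintf("landmark_set(): %s and %s only %.2f mm apart (need >= 10 mm)",
                   pr[1], pr[2], gap))
    }
  }
  structure(pts, class = "vc_landmarks")
}

required_landmarks <- function() {
  c("porion_l", "porion_r", "orbitale_l", "ans", "pns",
    "occlusal_anterior", "occlusal_molar_l", "occlusal_molar_r",
    "gonion_l", "gonion_r", "menton", "mental_foramen_l", "mental_foramen_r")
}

#' Canonical head coordinate frame
#'
#' Origin at the mid-porion point; `up` is the Frankfort-plane normal
#' oriented toward the cranium (ANS has negative up-coordinate); `anterior`
#' lies in the Frankfort plane pointing toward ANS; `left = up x anterior`
#' completes the right-handed triad.
#'
#' @param lm `vc_landmarks`.
#' @return `vc_frame` with fields `origin`, `up`, `anterior`, `left`.
#' @export
build_head_frame <- function(lm) {
  stopifnot(inherits(lm, "vc_landmarks"))
  fh <- frankfort_plane_raw(lm)
  origin <- (lm$porion_l + lm$porion_r) / 2
  up <- fh$normal
  # orient up so ANS (which sits below FH) has negative up-coordinate
  if (sum(up * (lm$ans - origin)) > 0) up <- -up
  a <- lm$ans - origin
  a_in <- a - sum(a * up) * up
  if (sqrt(sum(a_in^2)) < 1e-9) {
    stop("build_head_frame(): ANS projects onto the porion midpoint; frame undefined")
  }
  anterior <- unit3(a_in)
  left <- cross3(up, anterior)
  structure(list(origin = origin, up = up, anterior = anterior, left = left),
            class = "vc_frame")
}

# FH plane with arbitrary orientation (orientation fixed by callers)
frankfort_plane_raw <- function(lm) {
  if (!is.null(lm$orbitale_r)) {
    plane_fit(rbind(lm$porion_l, lm$porion_r, lm$orbitale_l, lm$orbitale_r))
  } else {
    plane_from_points(lm$porion_l, lm$porion_r, lm$orbitale_l)
  }
}

#' Frankfort horizontal plane
#'
#' Classical three-point FH through both porions and the left orbitale;
#' upgraded to a total-least-squares fit through all four points when the
#' right orbitale is supplied. Normal oriented superior.
#'
#' @param lm `vc_landmarks`.
#' @export
frankfort_plane <- function(lm) {
  frame <- build_head_frame(lm)
  orient_plane_along(frankfort_plane_raw(lm), frame$up)
}

#' Posterior coronal plane through both porions
#'
#' Contains both porions and the frame's up direction; normal is the
#' anterior axis, so the face is on the positive side.
#'
#' @param lm `vc_landmarks`.
#' @param frame `vc_frame` from [build_head_frame()].
#' @export
coronal_porion_plane <- function(lm, frame) {
  axis <- lm$porion_r - lm$porion_l
  n <- cross3(axis, frame$up)
  if (sqrt(sum(n^2)) < 1e-9) {
    stop("coronal_porion_plane(): porion axis parallel to up; degenerate")
  }
  pl <- orient_plane_along(plane(n, sum(n * lm$porion_l)), frame$anterior)
  if (signed_distance(pl, lm$ans) <= 0) {
    stop("coronal_porion_plane(): ANS not anterior of the porion axis; check landmarks")
  }
  pl
}

#' Bispinal (palatal) plane
#'
#' ANS-PNS is a line; the cutting plane contains it and the lateral axis of
#' the head frame (a transversely level palatal plane). Normal oriented
#' superior.
#'
#' @inheritParams coronal_porion_plane
#' @export
palatal_plane <- function(lm, frame) {
  dir <- lm$pns - lm$ans
  if (sqrt(sum(dir^2)) < 1e-9) stop("palatal_plane(): ANS equals PNS")
  n <- cross3(dir, frame$left)
  if (sqrt(sum(n^2)) < 1e-9) {
    stop("palatal_plane(): ANS-PNS direction parallel to the lateral axis")
  }
  orient_plane_along(plane(n, sum(n * lm$ans)), frame$up)
}

#' Functional occlusal plane
#'
#' Exact plane through the anterior occlusal point and the two molar
#' occlusal points; normal oriented superior.
#'
#' @inheritParams coronal_porion_plane
#' @export
occlusal_plane <- function(lm, frame) {
  pl <- plane_from_points(lm$occlusal_anterior, lm$occlusal_molar_l,
                          lm$occlusal_molar_r)
  orient_plane_along(pl, frame$up)
}

#' Mandibular base (gonion-menton) plane
#'
#' Exact plane through both gonions and menton; separates the face from the
#' neck. Normal oriented superior (face side positive).
#'
#' @inheritParams coronal_porion_plane
#' @export
mandibular_base_plane <- function(lm, frame) {
  pl <- plane_from_points(lm$gonion_l, lm$gonion_r, lm$menton)
  orient_plane_along(pl, frame$up)
}

#' Mental-foramina plane
#'
#' FH-parallel plane through the midpoint of the two mental foramina (an
#' FH-parallel plane cannot in general contain both foramina; the midpoint
#' rule is symmetric and deterministic, and each foramen's off-plane
#' residual is reported as an attribute).
#'
#' @inheritParams coronal_porion_plane
#' @export
mental_foramina_plane <- function(lm, frame) {
  mid <- (lm$mental_foramen_l + lm$mental_foramen_r) / 2
  pl <- plane(frame$up, sum(frame$up * mid))
  attr(pl, "foramen_residuals_mm") <- c(
    left = signed_distance(pl, lm$mental_foramen_l),
    right = signed_distance(pl, lm$mental_foramen_r)
  )
  pl
}

orient_plane_along <- function(pl, direction) {
  if (sum(pl$normal * direction) < 0) plane_flip(pl) else pl
}

#' Build the full cutting-plane stack
#'
#' Constructs the six planes of the protocol: Frankfort horizontal (upper
#' cut), bi-porion coronal (posterior cut), and the four slab separators
#' (palatal, occlusal, mental-foramina, mandibular base). Horizontal plane
#' normals point superior, the coronal normal points anterior.
#'
#' @param lm `vc_landmarks`.
#' @return `vc_plane_stack` with fields `fh`, `coronal_porion`, `palatal`,
#'   `occlusal`, `foramina`, `mandibular_base`, and the `frame` used.
#' @export
build_plane_stack <- function(lm) {
  frame <- build_head_frame(lm)
  structure(list(
    fh = frankfort_plane(lm),
    coronal_porion = coronal_porion_plane(lm, frame),
    palatal = palatal_plane(lm, frame),
    occlusal = occlusal_plane(lm, frame),
    foramina = mental_foramina_plane(lm, frame),
    mandibular_base = mandibular_base_plane(lm, frame),
    frame = frame
  ), class = "vc_plane_stack")
}

#' Sanity-check the plane stack ordering
#'
#' Along the vertical (up) line through ANS the planes must intersect in
#' superior-to-inferior order FH >= palatal >= occlusal >= foramina; menton
#' must lie on/below the foramina plane, ANS below FH and anterior of the
#' coronal plane. Returns a diagnostics data frame (one row per constraint,
#' with the measured gap in mm); segmentation refuses to run on any failure
#' unless forced.
#'
#' @param stack `vc_plane_stack`.
#' @param lm `vc_landmarks`.
#' @return data.frame with columns `constraint`, `gap_mm`, `pass`.
#' @export
validate_plane_stack <- function(stack, lm) {
  stopifnot(inherits(stack, "vc_plane_stack"), inherits(lm, "vc_landmarks"))
  up <- stack$frame$up
  hit <- function(pl) {
    # parameter along {ans + t * up} where the plane is crossed
    den <- sum(pl$normal * up)
    if (abs(den) < 1e-9) return(NA_real_)
    (pl$offset - sum(pl$normal * lm$ans)) / den
  }
  t_fh <- hit(stack$fh)
  t_pal <- hit(stack$palatal)
  t_occ <- hit(stack$occlusal)
  t_for <- hit(stack$foramina)
  rows <- list(
    c("fh_above_palatal", t_fh - t_pal),
    c("palatal_above_occlusal", t_pal - t_occ),
    c("occlusal_above_foramina", t_occ - t_for),
    c("ans_below_fh", t_fh),
    c("menton_on_or_below_foramina", -signed_distance(stack$foramina, lm$menton)),
    c("ans_anterior_of_coronal", signed_distance(stack$coronal_porion, lm$ans))
  )
  out <- data.frame(
    constraint = vapply(rows, `[`, "", 1L),
    gap_mm = as.numeric(vapply(rows, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  out$pass <- !is.na(out$gap_mm) & out$gap_mm >= 0
  out
}
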