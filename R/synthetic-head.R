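#' Parametric synthetic head specification
#'
#' The synthetic head is a smoothly lofted stack of superellipse
#' cross-sections: head-like enough that the full cephalometric plane stack
#' is valid and every slab is non-degenerate, deliberately not
#' photorealistic. Landmarks are placed analytically inside the surface in
#' a canonical frame (Frankfort plane at z = 0, bi-porion axis along x,
#' face toward +y), so the default planes are near-axis-aligned with mild
#' anatomical tilts (occlusal plane tilted posteriorly upward, gonions
#' above menton, asymmetric foramina heights).
#'
#' The three interior plane heights (`z_palatal`, `z_occlusal`,
#' `z_foramina`, mm below FH) are the calibration handles: moving one
#' reassigns volume between the two adjacent slabs and nothing else, which
#' is what makes closed-loop calibration to a target percentage
#' distribution well-posed.
#'
#' @param gender `"female"` or `"male"` preset tag.
#' @param scale global isotropic scale factor (volumes scale with its cube).
#' @param z_palatal,z_occlusal,z_foramina,z_base plane heights in mm
#'   (negative, below FH); must be strictly decreasing.
#' @param occlusal_tilt_mm molar occlusal points sit this far above the
#'   anterior occlusal point (posterior-up tilt), default 2.
#' @param gonion_rise_mm gonions sit this far above menton, default 8.
#' @param foramen_asym_mm left/right mental foramina sit this far below/above
#'   their mean height, default 1.
#' @param exponent superellipse exponent (2 = ellipse; ~2.4 fuller cheeks).
#' @param n_theta cross-section segments (resolution), default 48.
#' @param ring_mm vertical ring spacing in mm, default 4.
#' @param seed integer seed recorded with the spec (head generation itself
#'   is deterministic; the seed feeds cohort-level randomness).
#' @return `vc_headspec`.
#' @export
head_spec <- function(gender = c("female", "male"), scale = 1,
                      z_palatal = -32, z_occlusal = -52, z_foramina = -72,
                      z_base = -90, occlusal_tilt_mm = 2, gonion_rise_mm = 8,
                      foramen_asym_mm = 1, exponent = 2.4,
                      n_theta = 48L, ring_mm = 4, seed = 1L) {
  gender <- match.arg(gender)
  zs <- c(0, z_palatal, z_occlusal, z_foramina, z_base)
  if (any(diff(zs) >= 0)) {
    stop("head_spec(): need 0 > z_palatal > z_occlusal > z_foramina > z_base")
  }
  if (scale <= 0 || ring_mm <= 0 || n_theta < 12L) {
    stop("head_spec(): scale and ring_mm must be > 0, n_theta >= 12")
  }
  structure(list(
    gender = gender, scale = scale,
    z_palatal = z_palatal, z_occlusal = z_occlusal,
    z_foramina = z_foramina, z_base = z_base,
    occlusal_tilt_mm = occlusal_tilt_mm, gonion_rise_mm = gonion_rise_mm,
    foramen_asym_mm = foramen_asym_mm, exponent = exponent,
    n_theta = as.integer(n_theta), ring_mm = ring_mm, seed = as.integer(seed)
  ), class = "vc_headspec")
}

# half-width / half-depth profiles of the canonical loft (scale 1), mm
head_profile <- function() {
  list(
    z = c(78, 70, 55, 35, 10, 0, -15, -32, -45, -60, -75, -90, -105, -120),
    a = c(2, 28, 52, 64, 69, 70, 66, 60, 54, 50, 46, 41, 37, 35),
    b = c(2, 35, 62, 76, 84, 85, 82, 78, 73, 68, 62, 55, 48, 45)
  )
}

#' Generate a synthetic head mesh with consistent landmarks
#'
#' @param spec `vc_headspec`.
#' @return list with `mesh` (watertight, outward `vc_mesh`) and
#'   `landmarks` (`vc_landmarks`), both in mm.
#' @export
generate_head <- function(spec) {
  stopifnot(inherits(spec, "vc_headspec"))
  pr <- head_profile()
  afun <- stats::splinefun(pr$z, pr$a, method = "natural")
  bfun <- stats::splinefun(pr$z, pr$b, method = "natural")
  z_top <- max(pr$z)
  z_bot <- min(pr$z)
  zs <- seq(z_top, z_bot, by = -spec$ring_mm)
  if (zs[length(zs)] > z_bot) zs <- c(zs, z_bot)
  nt <- spec$n_theta
  th <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  p <- spec$exponent
  sc <- function(t, e) sign(t) * abs(t)^e
  cth <- sc(cos(th), 2 / p)
  sth <- sc(sin(th), 2 / p)

  nv <- length(zs) * nt
  v <- matrix(0, nrow = nv + 2L, ncol = 3L)
  for (i in seq_along(zs)) {
    a <- max(afun(zs[i]), 0.5)
    b <- max(bfun(zs[i]), 0.5)
    rows <- ((i - 1L) * nt + 1L):(i * nt)
    v[rows, 1L] <- a * cth
    v[rows, 2L] <- b * sth
    v[rows, 3L] <- zs[i]
  }
  apex_top <- nv + 1L
  apex_bot <- nv + 2L
  v[apex_top, ] <- c(0, 0, z_top + 2)
  v[apex_bot, ] <- c(0, 0, z_bot - 2)

  f <- vector("list", length(zs) + 1L)
  nxt <- c(2:nt, 1L)
  for (i in seq_len(length(zs) - 1L)) {
    r0 <- (i - 1L) * nt
    r1 <- i * nt
    # rings go downward; wind quads so normals point outward
    f[[i]] <- rbind(
      cbind(r0 + seq_len(nt), r1 + seq_len(nt), r0 + nxt),
      cbind(r0 + nxt, r1 + seq_len(nt), r1 + nxt)
    )
  }
  f[[length(zs)]] <- cbind(apex_top, seq_len(nt), nxt)              # top cone
  last <- (length(zs) - 1L) * nt
  f[[length(zs) + 1L]] <- cbind(apex_bot, last + nxt, last + seq_len(nt)) # bottom
  mesh <- trimesh(v * spec$scale, do.call(rbind, f))
  mesh <- mesh_repair_orientation(mesh)

  lm <- head_landmarks(spec)
  list(mesh = mesh, landmarks = lm)
}

# analytic landmark placement (canonical frame, then scaled)
head_landmarks <- function(spec) {
  s <- spec$scale
  z1 <- spec$z_palatal; z2 <- spec$z_occlusal
  z3 <- spec$z_foramina; z4 <- spec$z_base
  tilt <- spec$occlusal_tilt_mm
  lset <- list(
    porion_l = c(-60, 0, 0), porion_r = c(60, 0, 0),
    orbitale_l = c(-32, 62, 0), orbitale_r = c(32, 62, 0),
    ans = c(0, 70, z1), pns = c(0, 25, z1),
    occlusal_anterior = c(0, 66, z2),
    occlusal_molar_l = c(-28, 34, z2 + tilt),
    occlusal_molar_r = c(28, 34, z2 + tilt),
    gonion_l = c(-45, 15, z4 + spec$gonion_rise_mm),
    gonion_r = c(45, 15, z4 + spec$gonion_rise_mm),
    menton = c(0, 48, z4),
    mental_foramen_l = c(-22, 42, z3 - spec$foramen_asym_mm),
    mental_foramen_r = c(22, 42, z3 + spec$foramen_asym_mm)
  )
  landmark_set(lapply(lset, function(pt) pt * s))
}

#' Calibrate a head spec to a target percentage distribution
#'
#' Closed-loop calibration against the real measurement pipeline: the head
#' is generated, its lower two-thirds extracted, and the three interior
#' plane heights are adjusted by sequential bisection (top-down: palatal,
#' occlusal, foramina) until the measured cumulative shares match the
#' targets. Each bisection step cuts the already-extracted sub-mesh with
#' the exact plane the final landmark set will induce, so the verification
#' run reproduces the calibrated shares by construction.
#'
#' @param spec `vc_headspec`.
#' @param target_shares length-4 numeric (malar, maxillary, mandibular,
#'   chin), percent; must sum to 100 within 0.5.
#' @param tol_pp per-slab tolerance in percentage points (default 0.5; the
#'   bisection aims tighter internally).
#' @param max_iter bisection iterations per plane (default 50).
#' @return calibrated `vc_headspec` with attribute `measured_shares`.
#' @export
calibrate_to_distribution <- function(spec, target_shares, tol_pp = 0.5,
                                      max_iter = 50L) {
  target_shares <- as.numeric(target_shares)
  stopifnot(length(target_shares) == 4L, all(target_shares > 0))
  if (abs(sum(target_shares) - 100) > 0.5) {
    stop("calibrate_to_distribution(): target shares must sum to 100 within 0.5")
  }
  head <- generate_head(spec)
  stack <- build_plane_stack(head$landmarks)
  lower <- extract_lower_two_thirds(head$mesh, stack)
  total <- mesh_volume(lower)
  cum <- cumsum(target_shares)[1:3]

  # plane induced by the landmark set when the z-handle moves to `z`
  plane_at <- function(which, z) {
    sp2 <- spec
    sp2[[which]] <- z
    lm <- head_landmarks(sp2)
    frame <- build_head_frame(lm)
    switch(which,
      z_palatal = palatal_plane(lm, frame),
      z_occlusal = occlusal_plane(lm, frame),
      z_foramina = mental_foramina_plane(lm, frame)
    )
  }

  inner_tol <- min(tol_pp, 0.5) / 5
  bisect <- function(which, lo, hi, target_cum, sub_mesh) {
    # share above the plane is decreasing in z? no: plane lower => more
    # volume above => larger cumulative share; cumulative share is a
    # decreasing function of z. Bisect on that monotonicity.
    fz <- function(z) {
      pc <- cut_mesh(sub_mesh, plane_at(which, z))
      100 * (attr(sub_mesh, "vol_above_prior") %||% 0 + mesh_volume(pc$above)) / total
    }
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      val <- fz(mid)
      if (abs(val - target_cum) < inner_tol) return(mid)
      if (val > target_cum) lo <- mid else hi <- mid  # too much above: raise plane
      if (hi - lo < 1e-4 * abs(spec$z_base)) return((lo + hi) / 2)
    }
    stop(sprintf(
      "calibrate_to_distribution(): %s did not converge (last residual %.3f pp)",
      which, val - target_cum))
  }

  # bisection handles live in canonical (unscaled) coordinates; the induced
  # landmark set (and hence the plane) carries the spec's scale
  z1 <- bisect("z_palatal", spec$z_base + 4, -1, cum[1], lower)
  sub1 <- cut_mesh(lower, plane_at("z_palatal", z1))$below
  attr(sub1, "vol_above_prior") <- total - mesh_volume(sub1)
  z2 <- bisect("z_occlusal", spec$z_base + 3, z1 - 1, cum[2], sub1)
  sub2 <- cut_mesh(sub1, plane_at("z_occlusal", z2))$below
  attr(sub2, "vol_above_prior") <- total - mesh_volume(sub2)
  z3 <- bisect("z_foramina", spec$z_base + 1, z2 - 1, cum[3], sub2)

  out <- spec
  out$z_palatal <- z1
  out$z_occlusal <- z2
  out$z_foramina <- z3
  # verification through the full pipeline
  prof <- measure_head(out)
  measured <- c(prof$share_malar, prof$share_maxillary,
                prof$share_mandibular, prof$share_chin)
  resid <- measured - target_shares
  if (max(abs(resid)) > tol_pp) {
    stop(sprintf(
      "calibrate_to_distribution(): residuals exceed %.2f pp (max %.3f pp)",
      tol_pp, max(abs(resid))))
  }
  attr(out, "measured_shares") <- measured
  attr(out, "measured_total_mm3") <- prof$total
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure a synthetic head through the full pipeline
#'
#' Convenience wrapper: generate, build plane stack, validate, extract the
#' lower two-thirds, partition, and return the volume profile.
#'
#' @param spec `vc_headspec`.
#' @param force passed to [partition_slabs()].
#' @return `vc_profile`.
#' @export
measure_head <- function(spec, force = FALSE) {
  head <- generate_head(spec)
  measure_mesh(head$mesh, head$landmarks, force = force)
}

#' Measure any head mesh with its landmarks
#'
#' @param mesh watertight `vc_mesh`.
#' @param lm `vc_landmarks`.
#' @param force skip plane-stack validation failure (default FALSE).
#' @return `vc_profile`.
#' @export
measure_mesh <- function(mesh, lm, force = FALSE) {
  stack <- build_plane_stack(lm)
  lower <- extract_lower_two_thirds(mesh, stack)
  slabs <- partition_slabs(lower, stack, lm = lm, force = force)
  slab_volumes(slabs)
}

#' Rescale a head spec so the measured lower-two-thirds volume hits a target
#'
#' Uniform scaling preserves the percentage distribution exactly and scales
#' every volume with the cube of the factor.
#'
#' @param spec `vc_headspec` (ideally calibrated).
#' @param target_total_mm3 desired lower-two-thirds volume.
#' @return rescaled `vc_headspec`.
#' @export
scale_to_total <- function(spec, target_total_mm3) {
  cur <- attr(spec, "measured_total_mm3")
  if (is.null(cur)) cur <- measure_head(spec)$total
  out <- spec
  out$scale <- spec$scale * (target_total_mm3 / cur)^(1 / 3)
  attr(out, "measured_total_mm3") <- target_total_mm3
  attr(out, "measured_shares") <- attr(spec, "measured_shares")
  out
}
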