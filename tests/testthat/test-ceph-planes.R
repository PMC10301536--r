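canonical_lm <- function() {
  landmark_set(list(
    porion_l = c(-60, 0, 0), porion_r = c(60, 0, 0),
    orbitale_l = c(-30, 70, 0),
    ans = c(0, 90, -20), pns = c(0, 40, -20),
    occlusal_anterior = c(0, 80, -35),
    occlusal_molar_l = c(-28, 38, -35), occlusal_molar_r = c(28, 38, -35),
    gonion_l = c(-50, 10, -60), gonion_r = c(50, 10, -60),
    menton = c(0, 85, -75),
    mental_foramen_l = c(-25, 75, -62), mental_foramen_r = c(25, 75, -62)
  ))
}

test_that("landmark validation reports all problems at once", {
  pts <- unclass(canonical_lm())
  pts$pns <- NULL
  pts$menton <- NULL
  err <- tryCatch(landmark_set(pts), error = function(e) conditionMessage(e))
  expect_match(err, "pns")
  expect_match(err, "menton")

  pts2 <- unclass(canonical_lm())
  pts2$porion_r <- pts2$porion_l + c(2, 0, 0)
  expect_error(landmark_set(pts2), "10 mm")
})

test_that("head frame is canonical for axis-aligned landmarks and equivariant", {
  lm <- canonical_lm()
  fr <- build_head_frame(lm)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$up, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$anterior, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(abs(fr$left), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(sum(fr$up * fr$anterior), 0, tolerance = 1e-12)
  expect_equal(cross_check <- sum(fr$left * fr$up), 0, tolerance = 1e-12)

  set.seed(21)
  for (k in 1:5) {
    R <- random_rotation()
    tr <- stats::rnorm(3, 0, 40)
    lm2 <- transform_landmarks(lm, R, tr)
    fr2 <- build_head_frame(lm2)
    expect_equal(fr2$origin, as.numeric(R %*% fr$origin + tr), tolerance = 1e-9)
    expect_equal(fr2$up, as.numeric(R %*% fr$up), tolerance = 1e-9)
    expect_equal(fr2$anterior, as.numeric(R %*% fr$anterior), tolerance = 1e-9)
  }

  bad <- unclass(lm)
  bad$porion_r <- bad$porion_l + c(0, 0, 10.5)  # porion axis vertical-ish but
  bad$orbitale_l <- c(-30, 0, 5.25)             # collinear with orbitale
  bad$orbitale_l <- bad$porion_l + 0.5 * (bad$porion_r - bad$porion_l)
  expect_error(build_head_frame(landmark_set(bad)), "collinear")
})

test_that("frankfort plane: exact 3-point and fitted 4-point variants", {
  lm <- canonical_lm()
  fh <- frankfort_plane(lm)
  expect_equal(fh$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fh$offset, 0, tolerance = 1e-12)

  pts <- unclass(lm)
  pts$orbitale_r <- c(30, 70, 0.2)
  fh4 <- frankfort_plane(landmark_set(pts))
  ang <- acos(min(abs(sum(fh4$normal * c(0, 0, 1))), 1))
  expect_lt(ang, 0.003)

  pts$orbitale_r <- c(30, 70, 0)   # coplanar: exact plane again
  fh4b <- frankfort_plane(landmark_set(pts))
  expect_equal(abs(fh4b$normal[3]), 1, tolerance = 1e-12)
})

test_that("coronal plane contains the porions with the face on the positive side", {
  lm <- canonical_lm()
  fr <- build_head_frame(lm)
  cp <- coronal_porion_plane(lm, fr)
  expect_equal(cp$normal, c(0, 1, 0), tolerance = 1e-12)
  expect_lt(abs(signed_distance(cp, lm$porion_l)), 1e-9)
  expect_lt(abs(signed_distance(cp, lm$porion_r)), 1e-9)
  expect_equal(signed_distance(cp, lm$ans), 90, tolerance = 1e-9)

  # a frame whose anterior axis disagrees with the landmarks is rejected
  swapped <- unclass(lm)
  swapped$ans <- c(0, -90, -20)   # ANS behind the porion axis
  sl <- landmark_set(swapped)
  expect_error(coronal_porion_plane(sl, fr), "anterior")
})

test_that("palatal plane contains ANS/PNS, level transversely, tilt as constructed", {
  lm <- canonical_lm()
  fr <- build_head_frame(lm)
  pp <- palatal_plane(lm, fr)
  expect_equal(pp$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pp$offset, -20, tolerance = 1e-12)

  tilted <- unclass(lm)
  tilted$ans <- c(0, 90, -18)
  tilted$pns <- c(0, 40, -22)
  tl <- landmark_set(tilted)
  pp2 <- palatal_plane(tl, build_head_frame(tl))
  expect_lt(abs(signed_distance(pp2, tl$ans)), 1e-9)
  expect_lt(abs(signed_distance(pp2, tl$pns)), 1e-9)
  ang <- acos(min(abs(sum(pp2$normal * c(0, 0, 1))), 1))
  expect_equal(ang, atan2(4, 50), tolerance = 1e-9)  # 4.57 degrees
})

test_that("occlusal and mandibular-base planes pass through their landmarks, oriented up", {
  lm <- canonical_lm()
  fr <- build_head_frame(lm)
  op <- occlusal_plane(lm, fr)
  expect_equal(op$offset, -35, tolerance = 1e-12)
  expect_gt(sum(op$normal * fr$up), 0)

  asym <- unclass(lm)
  asym$occlusal_molar_l <- c(-28, 38, -34)
  asym$occlusal_molar_r <- c(28, 38, -36)
  al <- landmark_set(asym)
  op2 <- occlusal_plane(al, build_head_frame(al))
  for (nm in c("occlusal_anterior", "occlusal_molar_l", "occlusal_molar_r")) {
    expect_lt(abs(signed_distance(op2, al[[nm]])), 1e-9)
  }

  mb <- mandibular_base_plane(lm, fr)
  for (nm in c("gonion_l", "gonion_r", "menton")) {
    expect_lt(abs(signed_distance(mb, lm[[nm]])), 1e-9)
  }
  expect_gt(sum(mb$normal * fr$up), 0)
  expect_gt(signed_distance(mb, lm$occlusal_anterior), 0)
})

test_that("foramina plane is FH-parallel through the foramen midpoint", {
  lm <- canonical_lm()
  fr <- build_head_frame(lm)
  fp <- mental_foramina_plane(lm, fr)
  expect_equal(fp$offset, -62, tolerance = 1e-12)
  expect_equal(abs(sum(fp$normal * frankfort_plane(lm)$normal)), 1, tolerance = 1e-12)

  asym <- unclass(lm)
  asym$mental_foramen_l <- c(-25, 75, -61)
  asym$mental_foramen_r <- c(25, 75, -63)
  al <- landmark_set(asym)
  fp2 <- mental_foramina_plane(al, build_head_frame(al))
  expect_equal(fp2$offset, -62, tolerance = 1e-12)
  res <- attr(fp2, "foramen_residuals_mm")
  expect_equal(unname(res), c(1, -1), tolerance = 1e-12)
})

test_that("plane stack ordering is validated and violations localised", {
  lm <- canonical_lm()
  stack <- build_plane_stack(lm)
  diag <- validate_plane_stack(stack, lm)
  expect_true(all(diag$pass))
  expect_true(all(diag$gap_mm > 0))

  # raise the occlusal plane above the palatal plane
  bad <- unclass(lm)
  bad$occlusal_anterior[3] <- -15
  bad$occlusal_molar_l[3] <- -15
  bad$occlusal_molar_r[3] <- -15
  bl <- landmark_set(bad)
  d2 <- validate_plane_stack(build_plane_stack(bl), bl)
  expect_false(d2$pass[d2$constraint == "palatal_above_occlusal"])
  expect_true(d2$pass[d2$constraint == "fh_above_palatal"])

  # menton 0.5 mm above the foramina plane
  bad2 <- unclass(lm)
  bad2$menton[3] <- -61.5
  b2 <- landmark_set(bad2)
  d3 <- validate_plane_stack(build_plane_stack(b2), b2)
  row <- d3[d3$constraint == "menton_on_or_below_foramina", ]
  expect_false(row$pass)
  expect_equal(row$gap_mm, -0.5, tolerance = 1e-9)
})

test_that("all planes are rigid-motion equivariant", {
  lm <- canonical_lm()
  stack <- build_plane_stack(lm)
  probe <- rbind(c(10, 50, -30), c(-40, 20, -70), c(0, 90, -10))
  set.seed(5)
  for (k in 1:4) {
    R <- random_rotation()
    tr <- stats::rnorm(3, 0, 30)
    lm2 <- transform_landmarks(lm, R, tr)
    stack2 <- build_plane_stack(lm2)
    probe2 <- t(apply(probe, 1, function(p) R %*% p + tr))
    for (nm in c("fh", "coronal_porion", "palatal", "occlusal",
                 "foramina", "mandibular_base")) {
      expect_equal(signed_distance(stack2[[nm]], probe2),
                   signed_distance(stack[[nm]], probe),
                   tolerance = 1e-6)
    }
  }
})
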