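# fixtures built in code: no binary files in the repository

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# hollow "picture frame" solid: outer 4x4 footprint, 1x1 through-tunnel,
# z in [0, 2]; volume 30 mm^3; its cross-sections are loops with holes
frame_mesh <- function() {
  ring <- function(z) rbind(
    c(0, 0, z), c(4, 0, z), c(4, 4, z), c(0, 4, z),
    c(1.5, 1.5, z), c(2.5, 1.5, z), c(2.5, 2.5, z), c(1.5, 2.5, z)
  )
  v <- rbind(ring(0), ring(2))
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- NULL
  oo <- 1:4; ii <- 5:8; OO <- 9:12; II <- 13:16
  for (k in 1:4) {
    k2 <- k %% 4 + 1
    f <- rbind(f,
               quad(oo[k], oo[k2], OO[k2], OO[k]),
               quad(ii[k2], ii[k], II[k], II[k2]),
               quad(oo[k2], oo[k], ii[k], ii[k2]),
               quad(OO[k], OO[k2], II[k2], II[k]))
  }
  mesh_repair_orientation(trimesh(v, f))
}

# landmark set whose induced planes are exactly FH z = 0, coronal y = 0,
# palatal z = -40, occlusal z = -80, foramina z = -120, base z = -160
box_head_landmarks <- function() {
  landmark_set(list(
    porion_l = c(-60, 0, 0), porion_r = c(60, 0, 0),
    orbitale_l = c(-30, 70, 0),
    ans = c(0, 90, -40), pns = c(0, 40, -40),
    occlusal_anterior = c(0, 80, -80),
    occlusal_molar_l = c(-30, 40, -80), occlusal_molar_r = c(30, 40, -80),
    gonion_l = c(-50, 10, -160), gonion_r = c(50, 10, -160),
    menton = c(0, 80, -160),
    mental_foramen_l = c(-25, 75, -120), mental_foramen_r = c(25, 75, -120)
  ))
}

box_head_mesh <- function() {
  mesh_box(c(-100, -100, -220), c(100, 100, 20))
}

transform_landmarks <- function(lm, rotation, translation = c(0, 0, 0)) {
  landmark_set(lapply(unclass(lm), function(p) {
    as.numeric(rotation %*% p + translation)
  }))
}
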