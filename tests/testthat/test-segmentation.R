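test_that("box head gives exact box-arithmetic volumes", {
  mesh <- box_head_mesh()
  lm <- box_head_landmarks()
  stack <- build_plane_stack(lm)
  expect_true(all(validate_plane_stack(stack, lm)$pass))

  lower <- extract_lower_two_thirds(mesh, stack)
  # below z=0, anterior of y=0, above z=-160: 200 x 100 x 160
  expect_equal(mesh_volume(lower), 200 * 100 * 160, tolerance = 1e-9)
  expect_lt(mesh_volume(lower), mesh_volume(mesh))

  slabs <- partition_slabs(lower, stack, lm = lm)
  prof <- slab_volumes(slabs)
  expect_equal(prof$v_malar, 800000, tolerance = 1e-9)
  expect_equal(prof$v_maxillary, 800000, tolerance = 1e-9)
  expect_equal(prof$v_mandibular, 800000, tolerance = 1e-9)
  expect_equal(prof$v_chin, 800000, tolerance = 1e-9)
  expect_equal(
    unname(percentage_distribution(c(prof$v_malar, prof$v_maxillary,
                                     prof$v_mandibular, prof$v_chin))),
    c(25, 25, 25, 25))
})

test_that("slab volumes conserve the lower two-thirds exactly", {
  h <- generate_head(head_spec("female", n_theta = 32L, ring_mm = 6))
  stack <- build_plane_stack(h$landmarks)
  lower <- extract_lower_two_thirds(h$mesh, stack)
  slabs <- partition_slabs(lower, stack, lm = h$landmarks)
  prof <- slab_volumes(slabs)
  expect_equal(prof$total, mesh_volume(lower), tolerance = 1e-6)
  for (nm in c("malar", "maxillary", "mandibular", "chin")) {
    expect_true(mesh_is_watertight(slabs[[nm]]))
  }
})

test_that("slab volumes agree with the voxel oracle on the synthetic head", {
  h <- generate_head(head_spec("female", n_theta = 32L, ring_mm = 6))
  stack <- build_plane_stack(h$landmarks)
  lower <- extract_lower_two_thirds(h$mesh, stack)
  expect_equal(voxel_volume_oracle(lower, 1), mesh_volume(lower),
               tolerance = 0.02)
  slabs <- partition_slabs(lower, stack, lm = h$landmarks)
  for (nm in c("malar", "maxillary", "mandibular")) {
    m <- slabs[[nm]]
    expect_lt(abs(voxel_volume_oracle(m, 1) - mesh_volume(m)),
              mesh_surface_area(m) * 1)
  }
})

test_that("moving the occlusal plane inferiorly grows maxillary at mandibular's expense", {
  base <- head_spec("female", n_theta = 32L, ring_mm = 6)
  p0 <- measure_head(base)
  lower_spec <- base
  lower_spec$z_occlusal <- base$z_occlusal - 6
  p1 <- measure_head(lower_spec)
  expect_gt(p1$v_maxillary, p0$v_maxillary)
  expect_lt(p1$v_mandibular, p0$v_mandibular)
  expect_equal(p1$total, p0$total, tolerance = 1e-6)
})

test_that("slab volumes are rigid-motion invariant", {
  h <- generate_head(head_spec("female", n_theta = 28L, ring_mm = 7))
  p0 <- measure_mesh(h$mesh, h$landmarks)
  set.seed(17)
  for (k in 1:3) {
    R <- random_rotation()
    tr <- stats::rnorm(3, 0, 50)
    mesh2 <- mesh_transform(h$mesh, R, tr)
    lm2 <- transform_landmarks(h$landmarks, R, tr)
    p1 <- measure_mesh(mesh2, lm2)
    for (f in c("v_malar", "v_maxillary", "v_mandibular", "v_chin", "total")) {
      expect_equal(p1[[f]], p0[[f]], tolerance = 1e-6)
    }
  }
})

test_that("invalid plane stacks are refused unless forced", {
  mesh <- box_head_mesh()
  bad <- unclass(box_head_landmarks())
  bad$occlusal_anterior[3] <- -20   # occlusal above palatal
  bad$occlusal_molar_l[3] <- -20
  bad$occlusal_molar_r[3] <- -20
  bl <- landmark_set(bad)
  stack <- build_plane_stack(bl)
  lower <- extract_lower_two_thirds(mesh, stack)
  expect_error(partition_slabs(lower, stack, lm = bl), "validation failed")
  expect_warning(forced <- partition_slabs(lower, stack, lm = bl, force = TRUE),
                 "empty slab")
  expect_s3_class(forced, "vc_slabs")
  expect_true("maxillary" %in% forced$flags)
})
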