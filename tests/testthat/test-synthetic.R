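test_that("head generation is deterministic and passes its own validation", {
  spec <- head_spec("female", seed = 42L)
  h1 <- generate_head(spec)
  h2 <- generate_head(spec)
  expect_identical(h1$mesh$vertices, h2$mesh$vertices)
  expect_identical(h1$mesh$faces, h2$mesh$faces)
  expect_true(mesh_is_watertight(h1$mesh))
  expect_gt(mesh_volume(h1$mesh), 0)
  stack <- build_plane_stack(h1$landmarks)
  expect_true(all(validate_plane_stack(stack, h1$landmarks)$pass))
})

test_that("doubling the global scale scales every slab volume by 8", {
  s1 <- head_spec("female", n_theta = 32L, ring_mm = 6)
  s2 <- s1; s2$scale <- 2
  p1 <- measure_head(s1)
  p2 <- measure_head(s2)
  for (f in c("v_malar", "v_maxillary", "v_mandibular", "v_chin", "total")) {
    expect_equal(p2[[f]], 8 * p1[[f]], tolerance = 1e-6)
  }
  expect_equal(p2$share_malar, p1$share_malar, tolerance = 1e-6)
})

test_that("closed-loop calibration hits requested distributions within 0.5 pp", {
  targets <- list(
    symmetric = c(25, 25, 25, 25),
    female = c(38.7, 29.0, 27.6, 4.7),
    male = c(36.49119, 27.99987, 29.50343, 6.00551)
  )
  for (nm in names(targets)) {
    spec <- head_spec(if (nm == "male") "male" else "female",
                      n_theta = 36L, ring_mm = 5)
    cal <- calibrate_to_distribution(spec, targets[[nm]])
    measured <- attr(cal, "measured_shares")
    expect_lt(max(abs(measured - targets[[nm]])), 0.5)
    # re-measuring the calibrated spec reproduces the shares
    prof <- measure_head(cal)
    expect_equal(c(prof$share_malar, prof$share_maxillary,
                   prof$share_mandibular, prof$share_chin),
                 measured, tolerance = 1e-9)
  }
  expect_error(calibrate_to_distribution(head_spec("female"), c(40, 40, 40, 40)),
               "sum to 100")
})

test_that("scaling a calibrated head to a target total preserves its shares", {
  cal <- calibrate_to_distribution(head_spec("female", n_theta = 32L, ring_mm = 6),
                                   c(38.7, 29.0, 27.6, 4.7))
  scaled <- scale_to_total(cal, 732057)
  prof <- measure_head(scaled)
  expect_equal(prof$total, 732057, tolerance = 1e-6)
  expect_equal(prof$share_malar, attr(cal, "measured_shares")[1], tolerance = 1e-6)
})

test_that("cohort generation is deterministic and respects the degenerate-noise case", {
  cs0 <- cohort_spec(n_female = 2L, n_male = 1L, cv = 0, seed = 5L,
                     n_theta = 28L, ring_mm = 7)
  co <- generate_cohort(cs0, keep_meshes = FALSE)
  # cv = 0: every subject sits exactly on its gender preset
  fem <- co$table[co$table$gender == "female", ]
  preset <- gender_preset("female")
  for (i in seq_len(nrow(fem))) {
    shares <- 100 * as.numeric(fem[i, c("v_malar", "v_maxillary",
                                        "v_mandibular", "v_chin")]) /
      sum(fem[i, c("v_malar", "v_maxillary", "v_mandibular", "v_chin")])
    expect_lt(max(abs(shares - preset$shares)), 0.5)
  }
  expect_identical(fem$v_malar[1], fem$v_malar[2])

  co2 <- generate_cohort(cs0, keep_meshes = FALSE)
  expect_identical(co$table, co2$table)
})

test_that("jury-score generator hits its target test-retest correlation", {
  ids <- sprintf("s%03d", 1:155)
  cs <- cohort_spec(target_r = 0.7, seed = 31L)
  sc <- generate_jury_scores(cs, ids)
  jr <- judge_repeatability(sc)
  ok <- abs(jr$per_judge$r - 0.7) <= 0.1
  expect_gte(sum(ok), 5)

  cs1 <- cohort_spec(target_r = 1, seed = 31L)
  sc1 <- generate_jury_scores(cs1, ids)
  s1 <- sc1[sc1$session == 1L, ]
  s2 <- sc1[sc1$session == 2L, ]
  expect_identical(s1$score, s2$score)
  expect_equal(judge_repeatability(sc1)$mean_r, 1)
})

test_that("selection fraction matches the Gaussian-tail expectation", {
  ids <- sprintf("s%03d", 1:155)
  cs <- cohort_spec(target_r = 0.7, score_mean = 7, score_sd = 1, seed = 13L)
  sc <- generate_jury_scores(cs, ids)
  sel <- select_attractive(sc, 8.5)
  # mean over 6 judges x 2 sessions: latent + mean bias + mean session noise
  sd_noise <- 1 * sqrt(1 / 0.7 - 1)
  sd_mean <- sqrt(1 + cs$judge_bias_sd^2 / 6 + sd_noise^2 / 12)
  expected <- stats::pnorm(8.5, mean = 7, sd = sd_mean, lower.tail = FALSE)
  expect_lt(abs(length(sel) / 155 - expected), 0.03)
})
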