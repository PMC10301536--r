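test_that("axis-aligned and central cuts give analytic piece volumes", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  cc <- cut_mesh(cube, plane(c(0, 0, 1), 0.3))
  expect_equal(mesh_volume(cc$above), 0.7, tolerance = 1e-12)
  expect_equal(mesh_volume(cc$below), 0.3, tolerance = 1e-12)
  expect_true(mesh_is_watertight(cc$above))
  expect_true(mesh_is_watertight(cc$below))

  sp <- mesh_icosphere(radius = 10, subdivisions = 4L)
  h <- cut_mesh(sp, plane(c(0, 0, 1), 0))
  expect_equal(mesh_volume(h$above), 2 / 3 * pi * 1000, tolerance = 0.005)
  expect_equal(mesh_volume(h$below), 2 / 3 * pi * 1000, tolerance = 0.005)

  miss <- cut_mesh(cube, plane(c(0, 0, 1), 5))
  expect_true(mesh_is_empty(miss$above))
  expect_equal(mesh_volume(miss$below), 1)
})

test_that("cut pieces conserve volume for random planes (property)", {
  set.seed(42)
  sp <- mesh_icosphere(radius = 10, subdivisions = 3L)
  frame <- frame_mesh()
  for (k in 1:12) {
    mesh <- if (k %% 2 == 0) sp else frame
    n <- stats::rnorm(3)
    off <- stats::runif(1, -3, 3)
    pc <- cut_mesh(mesh, plane(n, off))
    total <- mesh_volume(pc$above) + mesh_volume(pc$below)
    expect_equal(total, mesh_volume(mesh), tolerance = 1e-6)
    if (!mesh_is_empty(pc$above)) expect_true(mesh_is_watertight(pc$above))
    if (!mesh_is_empty(pc$below)) expect_true(mesh_is_watertight(pc$below))
  }
})

test_that("cutting the kept side again by the same plane is a no-op", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  pl <- plane(c(1, 2, 3), 1.2)
  cc <- cut_mesh(cube, pl)
  again <- cut_mesh(cc$above, pl)
  expect_true(mesh_is_empty(again$below))
  expect_equal(mesh_volume(again$above), mesh_volume(cc$above), tolerance = 1e-12)
})

test_that("cross-sections with holes are capped watertight", {
  frame <- frame_mesh()
  expect_equal(mesh_volume(frame), 30)
  cc <- cut_mesh(frame, plane(c(0, 0, 1), 1))
  expect_equal(mesh_volume(cc$above), 15, tolerance = 1e-9)
  expect_equal(mesh_volume(cc$below), 15, tolerance = 1e-9)
  expect_true(mesh_is_watertight(cc$above))
  expect_true(mesh_is_watertight(cc$below))
  # oblique cut through outer wall and tunnel at once
  cc2 <- cut_mesh(frame, plane(c(0.2, 0.1, 1), 1))
  expect_equal(mesh_volume(cc2$above) + mesh_volume(cc2$below), 30,
               tolerance = 1e-9)
})

test_that("non-watertight input is refused", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  open <- trimesh(cube$vertices, cube$faces[-1, , drop = FALSE])
  expect_error(cut_mesh(open, plane(c(0, 0, 1), 0.5)), "not watertight")
})
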