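test_that("plane-triangle solid angle matches analytic cases", {
  # one octant of a sphere-like triangle seen from the origin: 4*pi/8
  tri <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  w <- triangle_solid_angle(tri, c(0, 0, 0))
  expect_equal(abs(as.numeric(w)), pi / 2, tolerance = 1e-12)
  # coplanar observer outside the triangle: zero, not singular
  w2 <- triangle_solid_angle(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             c(2, 2, 0))
  expect_equal(as.numeric(w2), 0)
  expect_false(attr(w2, "singular"))
  # observer on the interior: zero with the singular flag
  w3 <- triangle_solid_angle(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             c(0.2, 0.2, 0))
  expect_equal(as.numeric(w3), 0)
  expect_true(attr(w3, "singular"))
})

test_that("solid angles over a closed mesh sum to 4*pi from inside", {
  ico <- make_icosphere(3, 10)
  pts <- rbind(c(0, 0, 0), c(3, -2, 5), c(-6, 1, 1))
  W <- ecgimap:::solid_angle_matrix(ico$vertices, ico$faces, pts)
  expect_equal(rowSums(W), rep(4 * pi, 3), tolerance = 1e-6 * 4 * pi)
  # from outside the sum vanishes
  W0 <- ecgimap:::solid_angle_matrix(ico$vertices, ico$faces,
                                     matrix(c(50, 0, 0), 1))
  expect_lt(abs(sum(W0)), 1e-9)
})

test_that("analytic sphere transfer follows the shell solution", {
  expect_equal(analytic_sphere_transfer(0, 1, 2), 1)
  expect_equal(analytic_sphere_transfer(1, 1, 2), 0.6)
  ratios <- vapply(0:5, analytic_sphere_transfer, 0, a = 50, b = 150)
  expect_true(all(diff(ratios) < 0))
  expect_error(analytic_sphere_transfer(1, 2, 1), "a < b")
  expect_error(analytic_sphere_transfer(-1, 1, 2), "non-negative")
})

test_that("BEM transfer preserves constants and reproduces harmonics", {
  pair <- sphere_pair(3)
  nH <- nrow(pair$heart$mesh$vertices)
  ones <- rep(1, nH)
  expect_lt(max(abs(pair$transfer$torso_entries %*% ones - 1)), 1e-3)
  errs <- vapply(1:3, function(l) harmonic_transfer_error(pair, l), 0)
  expect_true(all(errs < 0.05))
  # refinement decreases the error
  coarse <- sphere_pair(2)
  errs2 <- vapply(1:3, function(l) harmonic_transfer_error(coarse, l), 0)
  expect_true(all(errs < errs2))
})

test_that("constant preservation holds on the anatomical geometry", {
  g <- small_geometry()
  ones <- rep(1, ncol(g$transfer$entries))
  expect_lt(max(abs(g$transfer$entries %*% ones - 1)), 1e-3)
  expect_lt(max(abs(g$transfer$torso_entries %*% ones - 1)), 1e-3)
})

test_that("assembly rejects open meshes and fixes inward orientation", {
  heart <- list(mesh = make_icosphere(1, 50))
  torso <- list(mesh = make_icosphere(1, 150, label = "TORSO"),
                electrode_vertex_ids = NULL, limb_lead_ids = NULL)
  open_torso <- torso
  open_torso$mesh$faces <- open_torso$mesh$faces[-1L, , drop = FALSE]
  expect_error(build_bem_system(heart, open_torso), "not closed")
  # flipping every torso face is repaired by auto-orientation
  flipped <- torso
  flipped$mesh$faces <- flipped$mesh$faces[, c(1L, 3L, 2L)]
  sys <- build_bem_system(heart, flipped)
  tr <- build_transfer_matrix(sys)
  ones <- rep(1, nrow(heart$mesh$vertices))
  expect_lt(max(abs(tr$torso_entries %*% ones - 1)), 1e-3)
})

test_that("forward projection is linear, shift-equivariant and strict", {
  pair <- sphere_pair(2)
  nH <- nrow(pair$heart$mesh$vertices)
  set.seed(1)
  x1 <- matrix(rnorm(nH * 5), nH)
  x2 <- matrix(rnorm(nH * 5), nH)
  tr <- pair$transfer
  expect_equal(forward_project(x1 + x2, tr, rows = "torso"),
               forward_project(x1, tr, rows = "torso") +
                 forward_project(x2, tr, rows = "torso"),
               tolerance = 1e-12)
  expect_equal(forward_project(2 * x1, tr, rows = "torso"),
               2 * forward_project(x1, tr, rows = "torso"),
               tolerance = 1e-12)
  expect_equal(forward_project(matrix(0, nH, 3), tr, rows = "torso"),
               matrix(0, nrow(pair$torso$mesh$vertices), 3))
  # a static operator commutes with a time shift
  shifted <- x1[, c(5L, 1:4)]
  expect_equal(forward_project(shifted, tr, rows = "torso"),
               forward_project(x1, tr, rows = "torso")[, c(5L, 1:4)],
               tolerance = 1e-12)
  xbad <- x1
  xbad[3, 2] <- NaN
  expect_error(forward_project(xbad, tr, rows = "torso"), "non-finite|NA")
})
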