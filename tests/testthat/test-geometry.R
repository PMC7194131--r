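test_that("synthetic heart matches the target resolution and is closed", {
  h <- make_synthetic_heart(4000, seed = 1)
  n <- nrow(h$mesh$vertices)
  expect_gte(n, 3200)
  expect_lte(n, 4800)
  expect_true(mesh_is_closed(h$mesh))
  expect_equal(mean_edge_length(h$mesh), 3.6, tolerance = 0.3)
  expect_setequal(unique(h$mesh$labels), c("EPI", "LV_ENDO", "RV_ENDO"))
  expect_gt(mesh_signed_volume(orient_faces_outward(h$mesh)), 0)
})

test_that("heart build is deterministic per seed and validates parameters", {
  h1 <- make_synthetic_heart(800, seed = 3)
  h2 <- make_synthetic_heart(800, seed = 3)
  expect_identical(h1$mesh$vertices, h2$mesh$vertices)
  expect_identical(h1$mesh$faces, h2$mesh$faces)
  expect_error(make_synthetic_heart(800, wall_params = list(wall_thickness = -1)),
               "positive")
  expect_error(make_synthetic_heart(100), ">= 500")
})

test_that("a 500-node heart still carries all 17 assignable segments", {
  h <- make_synthetic_heart(500, seed = 2)
  expect_true(mesh_is_closed(h$mesh))
  seg <- assign_aha_segments(h)
  expect_setequal(sort(unique(seg$segment_id)), 1:17)
  seg2 <- apply_rv_septal_substitution(seg, h)
  expect_true(attr(seg2, "substitution_applied"))
})

test_that("synthetic torso holds 128 distinct on-surface electrodes", {
  g <- small_geometry()
  to <- g$torso
  expect_true(mesh_is_closed(to$mesh))
  expect_length(unique(to$electrode_vertex_ids), 128L)
  expect_length(to$limb_lead_ids, 4L)
  expect_false(any(to$limb_lead_ids %in% to$electrode_vertex_ids))
  # heart strictly inside the torso
  expect_true(all(points_in_mesh(to$mesh, g$heart$mesh$vertices)))
  # electrode vertices lie outside the heart
  epts <- to$mesh$vertices[to$electrode_vertex_ids, ]
  expect_false(any(points_in_mesh(g$heart$mesh, epts)))
})

test_that("a heart overlapping the torso wall is rejected", {
  h <- make_synthetic_heart(500, seed = 2)
  big <- h
  big$mesh$vertices <- big$mesh$vertices * 5
  expect_error(make_synthetic_torso(big), "fit|inside")
})

test_that("segment assignment partitions nodes and matches hand geometry", {
  g <- small_geometry()
  seg <- assign_aha_segments(g$heart)
  expect_equal(nrow(seg), nrow(g$heart$mesh$vertices))
  expect_true(all(seg$segment_id %in% 1:17))
  # apex vertex falls in the apical cap
  expect_equal(seg$segment_id[g$heart$apex_point], 17L)
  # hand-placed nodes (septal = +x, base-to-apex = -z, so the 90-degree
  # anterior direction is -y): basal anterior -> 1, mid anterior -> 7,
  # apical septal -> 14, long-axis anchor at the cap -> 17
  v <- rbind(c(0, 0, 0),
             c(0, -35, -10),
             c(0, -30, -40),
             c(20, 0, -75),
             c(0, 0, -100))
  mesh <- triangle_mesh(v, matrix(1:3, 1), rep("EPI", 5))
  hg <- heart_geometry(mesh, apex_point = 5L, base_center = c(0, 0, 0),
                       long_axis = c(0, 0, -1),
                       septal_direction = c(1, 0, 0))
  s <- assign_aha_segments(hg)
  expect_equal(s$segment_id[2:5], c(1L, 7L, 14L, 17L))
})

test_that("segment ids are invariant under rigid-body transformation", {
  g <- small_geometry()
  seg <- assign_aha_segments(g$heart)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  shift <- c(12, -30, 55)
  h2 <- g$heart
  h2$mesh <- rigid_transform_mesh(h2$mesh, R, shift)
  h2$base_center <- as.vector(R %*% g$heart$base_center) + shift
  h2$long_axis <- as.vector(R %*% g$heart$long_axis)
  h2$septal_direction <- as.vector(R %*% g$heart$septal_direction)
  seg2 <- assign_aha_segments(h2)
  expect_identical(seg2$segment_id, seg$segment_id)
})

test_that("RV septal substitution touches exactly the five septal segments", {
  g <- small_geometry()
  seg <- assign_aha_segments(g$heart)
  seg2 <- apply_rv_septal_substitution(seg, g$heart)
  expect_setequal(rv_substitution_segments(), c(2L, 3L, 8L, 9L, 14L))
  surro <- seg2$surface_class == "EPI_SURROGATE" & !is.na(seg2$surface_class)
  expect_setequal(unique(seg2$segment_id[surro]), rv_substitution_segments())
  expect_true(all(seg2$surface_label[surro] == "RV_ENDO"))
  # non-septal epicardial segments are untouched
  outside <- !(seg$segment_id %in% rv_substitution_segments())
  expect_identical(seg2$surface_class[outside], seg$surface_class[outside])
  # degenerate axis errors
  bad <- g$heart
  bad$long_axis <- c(0, 0, 0)
  expect_error(assign_aha_segments(bad), "degenerate")
})
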