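line_skeleton <- function(n = 21) {
  sk <- array(FALSE, c(n + 4, 7, 7))
  sk[3:(n + 2), 4, 4] <- TRUE
  sk
}

test_that("a straight tube thins to a single 1-voxel-wide axial path", {
  sc <- tube_scene(radius_mm = 0.2, noise = 0)
  sk <- skeletonize_3d(sc$mask)
  A <- vascumet:::skeleton_adjacency(sk)
  deg <- vapply(A$adj, length, integer(1))
  expect_true(all(deg <= 2))
  expect_equal(sum(deg <= 1), 2)          # exactly two endpoints
  expect_equal(max(label_components(sk)), 1)
  gr <- skeleton_to_graph(sk, spacing_mm = 0.1)
  expect_equal(nrow(gr$nodes), 2)
  expect_equal(nrow(gr$edges), 1)
  expect_equal(gr$edges$tortuosity, 1, tolerance = 1e-6)
})

test_that("skeletonization preserves connectedness of the mask", {
  for (s in c(2, 3)) {
    tr <- generate_vessel_tree(seed = s, branching_depth = 1)
    ras <- rasterize_vessel_tree(tr, vox_grid(c(80, 80, 80), 0.1))
    sk <- skeletonize_3d(ras$mask)
    expect_equal(max(label_components(sk)),
                 max(label_components(ras$mask)))
  }
  expect_error(skeletonize_3d(array(FALSE, c(5, 5, 5))), "empty")
})

test_that("a solid sphere collapses to a few central voxels", {
  d <- c(21, 21, 21)
  co <- expand.grid(x = 1:21, y = 1:21, z = 1:21)
  ball <- array((co$x - 11)^2 + (co$y - 11)^2 + (co$z - 11)^2 <= 64, d)
  sk <- skeletonize_3d(ball)
  expect_lte(sum(sk), 10)
  idx <- which(sk, arr.ind = TRUE)
  expect_true(all(abs(idx - 11) <= 8))  # inside the ball
})

test_that("a straight 21-voxel path maps to 2 nodes and a 2.0 mm edge", {
  gr <- skeleton_to_graph(line_skeleton(21), spacing_mm = 0.1)
  expect_equal(nrow(gr$nodes), 2)
  expect_equal(nrow(gr$edges), 1)
  expect_equal(gr$edges$length_mm, 2.0, tolerance = 1e-12)
  expect_equal(gr$edges$chord_mm, 2.0, tolerance = 1e-12)
  expect_equal(gr$edges$tortuosity, 1.0, tolerance = 1e-12)
})

test_that("a Y-shaped skeleton yields 4 nodes (3 tips + 1 junction), 3 edges", {
  sk <- array(FALSE, c(21, 21, 5))
  sk[3:11, 11, 3] <- TRUE                      # stem
  for (i in 1:7) sk[11 + i, 11 + i, 3] <- TRUE # upper arm (diagonal)
  for (i in 1:7) sk[11 + i, 11 - i, 3] <- TRUE # lower arm
  gr <- skeleton_to_graph(sk, spacing_mm = 0.1, prune_spur_mm = 0)
  expect_equal(nrow(gr$nodes), 4)
  expect_equal(nrow(gr$edges), 3)
  expect_equal(sort(gr$nodes$degree), c(1, 1, 1, 3))
})

test_that("an isolated voxel is a node with no edges", {
  sk <- array(FALSE, c(5, 5, 5)); sk[3, 3, 3] <- TRUE
  gr <- skeleton_to_graph(sk, spacing_mm = 0.1)
  expect_equal(nrow(gr$nodes), 1)
  expect_equal(nrow(gr$edges), 0)
})

test_that("a semicircular tube recovers tortuosity 2/pi within 5% at
           0.05 mm voxels", {
  g <- vox_grid(c(60, 40, 13), 0.05)
  tr <- vessel_tree(list(semicircle_branch(1, 0.1, center = c(1.4, 0.5, 0.3),
                                           n_points = 361)))
  ras <- rasterize_vessel_tree(tr, g)
  gr <- skeleton_to_graph(skeletonize_3d(ras$mask), spacing_mm = 0.05)
  expect_equal(nrow(gr$edges), 1)
  expect_lt(abs(gr$edges$tortuosity - 2 / pi) / (2 / pi), 0.05)
})

test_that("node-free cycles are traced as loops", {
  # diamond ring of diagonal steps: every voxel has exactly two neighbors
  sk <- array(FALSE, c(23, 23, 3))
  for (i in -5:5) {
    sk[12 + i, 12 + (5 - abs(i)), 2] <- TRUE
    if (abs(i) < 5) sk[12 + i, 12 - (5 - abs(i)), 2] <- TRUE
  }
  gr <- skeleton_to_graph(sk, spacing_mm = 0.1, prune_spur_mm = 0,
                          consolidate = FALSE)
  expect_equal(nrow(gr$edges), 1)
  expect_equal(gr$edges$from, gr$edges$to)
  expect_equal(gr$edges$length_mm, 20 * sqrt(2) * 0.1, tolerance = 1e-9)
})

test_that("vessel summary aggregates edges and mask volume", {
  msk <- array(FALSE, c(20, 20, 20)); msk[seq_len(1000)] <- TRUE
  gr <- skeleton_to_graph(line_skeleton(21), spacing_mm = 0.1)
  s <- vessel_summary(gr, msk, 0.1)
  expect_equal(s$vessel_volume_mm3, 1.0)
  expect_equal(s$mean_length_mm, s$min_length_mm)
  expect_equal(s$mean_length_mm, s$max_length_mm)
  expect_equal(s$mean_tortuosity, 1.0, tolerance = 1e-12)
  # empty graph: flagged record, not zeros
  e <- vessel_summary(structure(list(nodes = data.frame(), edges = data.frame(),
                                     paths = list(), spacing_mm = rep(0.1, 3)),
                                class = "vessel_graph"),
                      array(FALSE, c(4, 4, 4)), 0.1)
  expect_true(e$empty)
  expect_true(is.na(e$mean_length_mm))
})

test_that("tree phantom morphometry matches ground truth", {
  tr <- generate_vessel_tree(seed = 0)
  g <- vox_grid(c(80, 80, 80), 0.1)
  ras <- rasterize_vessel_tree(tr, g)
  sk <- skeletonize_3d(ras$mask)
  gr <- skeleton_to_graph(sk, radius_map_from_mask(ras$mask, 0.1), 0.1)
  s <- vessel_summary(gr, ras$mask, 0.1)
  expect_equal(s$n_nodes, tr$truth_summary$n_nodes)
  expect_lt(abs(s$vessel_volume_mm3 - tr$truth_summary$vessel_volume_mm3) /
              tr$truth_summary$vessel_volume_mm3, 0.15)
  expect_lt(abs(s$mean_length_mm - mean(tr$truth$length_mm)) /
              mean(tr$truth$length_mm), 0.10)
  expect_true(all(gr$edges$tortuosity > 0 & gr$edges$tortuosity <= 1 + 1e-12))
})
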