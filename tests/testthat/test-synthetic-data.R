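# --- vessel trees ------------------------------------------------------------

test_that("a straight depth-0 root has tortuosity 1 and two endpoint nodes", {
  tr <- generate_vessel_tree(seed = 7, n_roots = 1, branching_depth = 0,
                             branch_length_mm = c(2, 2), curvature = 0)
  expect_equal(nrow(tr$truth), 1)
  expect_equal(tr$truth$tortuosity, 1.0, tolerance = 1e-12)
  expect_equal(tr$truth$length_mm, 2.0, tolerance = 1e-9)
  expect_equal(tr$truth_summary$n_nodes, 2)
})

test_that("a semicircular branch has truth tortuosity 2/pi", {
  tr <- vessel_tree(list(semicircle_branch(1.5, 0.2, n_points = 721)))
  expect_equal(tr$truth$tortuosity, 2 / pi, tolerance = 1e-4)
  expect_equal(tr$truth$chord_mm, 3.0, tolerance = 1e-9)
})

test_that("tree generation is deterministic and truth tortuosity <= 1", {
  a <- generate_vessel_tree(seed = 1)
  b <- generate_vessel_tree(seed = 1)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  for (s in 0:4) {
    tr <- generate_vessel_tree(seed = s)
    expect_true(all(tr$truth$tortuosity <= 1 + 1e-12))
    expect_true(all(tr$truth$radius_mm > 0))
  }
})

test_that("an impossible tree errors instead of escaping the domain", {
  expect_error(
    generate_vessel_tree(seed = 1, domain_mm = c(1, 1, 1),
                         branch_length_mm = c(2, 2.5),
                         radius_range_mm = c(0.05, 0.2)),
    "domain too small"
  )
})

# --- rasterization -----------------------------------------------------------

test_that("rasterized tube volume approximates the analytic cylinder volume", {
  g <- vox_grid(c(60, 20, 20), 0.1)
  tr <- vessel_tree(list(straight_branch(c(0.5, 1, 1), c(4.5, 1, 1), 0.2)))
  ras <- rasterize_vessel_tree(tr, g)
  analytic <- pi * 0.2^2 * 4
  expect_lt(abs(sum(ras$mask) * 0.1^3 - analytic) / analytic, 0.15)
  # radius map carries the local truth radius on vessel voxels
  expect_equal(unique(ras$radius_map[ras$mask]), 0.2)
})

test_that("rasterization error decreases as the voxel size shrinks", {
  tr <- vessel_tree(list(straight_branch(c(0.5, 1, 1), c(4.5, 1, 1), 0.2)))
  err <- sapply(c(0.1, 0.05), function(sp) {
    g <- vox_grid(round(c(5 / sp, 2 / sp, 2 / sp)), sp)
    v <- sum(rasterize_vessel_tree(tr, g)$mask) * sp^3
    abs(v - pi * 0.2^2 * 4)
  })
  expect_lt(err[2], err[1])
})

test_that("empty trees and disjoint tubes rasterize with correct topology", {
  g <- vox_grid(c(30, 30, 30), 0.1)
  expect_true(all(!rasterize_vessel_tree(vessel_tree(list()), g)$mask))
  tr2 <- vessel_tree(list(
    straight_branch(c(0.3, 0.8, 0.8), c(2.7, 0.8, 0.8), 0.15),
    straight_branch(c(0.3, 2.2, 2.2), c(2.7, 2.2, 2.2), 0.15)
  ))
  lab <- label_components(rasterize_vessel_tree(tr2, g)$mask)
  expect_equal(max(lab), 2)
})

test_that("sub-voxel branches warn and keep a one-voxel centerline", {
  g <- vox_grid(c(30, 10, 10), 0.1)
  tr <- vessel_tree(list(straight_branch(c(0.3, 0.5, 0.5), c(2.7, 0.5, 0.5),
                                         0.02)))
  expect_warning(ras <- rasterize_vessel_tree(tr, g), "centerline")
  expect_true(sum(ras$mask) >= 24)  # a connected line of voxels exists
  expect_equal(max(label_components(ras$mask)), 1)
})

# --- plasma input ------------------------------------------------------------

test_that("plasma input has one early peak, monotone washout, finite integral", {
  tt <- seq(0, 3600, by = 1)
  inp <- simulate_plasma_input(tt)
  expect_true(all(inp$Cp >= 0))
  pk <- which.max(inp$Cp)
  expect_lt(tt[pk], 120)
  post <- inp$Cp[tt >= tt[pk]]
  expect_true(all(diff(post) <= 1e-9))
  auc <- sum(diff(tt) * (head(inp$Cp, -1) + tail(inp$Cp, -1)) / 2)
  expect_true(is.finite(auc) && auc > 0)
})

test_that("plasma input degenerate modes behave as stated", {
  tt <- seq(0, 100, by = 1)
  expect_equal(simulate_plasma_input(tt, peak_value = 3,
                                     mode = "constant")$Cp,
               rep(3, length(tt)))
  expect_equal(simulate_plasma_input(tt, peak_value = 0)$Cp,
               rep(0, length(tt)))
  expect_error(simulate_plasma_input(c(0, 5, 5, 10)), "increasing")
  expect_error(input_function(c(0, 1), c(1, -1)), "non-negative")
})

# --- dynamic PET forward simulation ------------------------------------------

test_that("zero kinetics give a zero 4D volume; seeds reproduce noise", {
  g <- vox_grid(c(4, 4, 4), 0.5)
  lab <- array(1L, g$dim)
  tt <- seq(0, 3630, by = 5)
  inp <- simulate_plasma_input(tt)
  sched <- petrus_schedule()
  dp0 <- simulate_dynamic_pet(lab, list(kinetic_params(0, 0, 0)), inp, sched, g)
  expect_true(all(dp0$data == 0))
  dpa <- simulate_dynamic_pet(lab, list(kinetic_params(0.1, 0.2, 0.05)),
                              inp, sched, g, noise_scale = 0.5, seed = 9)
  dpb <- simulate_dynamic_pet(lab, list(kinetic_params(0.1, 0.2, 0.05)),
                              inp, sched, g, noise_scale = 0.5, seed = 9)
  expect_identical(dpa$data, dpb$data)
  expect_error(simulate_dynamic_pet(lab, list(list(K1 = -1, k2 = 0, k3 = 0)),
                                    inp, sched, g), "non-negative")
})

test_that("with k2 = 0 and constant input the late uptake slope is K1*Cp", {
  g <- vox_grid(c(1, 1, 1), 1)
  lab <- array(1L, c(1, 1, 1))
  tt <- seq(0, 3630, by = 1)
  inp <- simulate_plasma_input(tt, peak_value = 10, mode = "constant")
  sched <- petrus_schedule()
  dp <- simulate_dynamic_pet(lab, list(kinetic_params(0.1, 0, 0.05)),
                             inp, sched, g, noise_scale = 0)
  tac <- dp$data[1, 1, 1, ]
  mids <- frame_midpoints(sched) / 60  # minutes
  late <- mids >= 20
  slope <- coef(lm(tac[late] ~ mids[late]))[2]
  expect_equal(unname(slope), 0.1 * 10, tolerance = 0.01)
})

# --- ultrafast stacks ---------------------------------------------------------

test_that("noiseless bloodless stacks have exactly the configured rank", {
  m <- vessel_plane_mask()
  for (r in c(1, 3)) {
    sc <- simulate_ultrafast_stack(m, tissue_rank = r, tissue_amp = 50,
                                   blood_amp = 0, noise_amp = 0, seed = 2)
    d <- svd(matrix(sc$stack, 48 * 48, 300), nu = 0, nv = 0)$d
    expect_gt(d[r], 1e-6)
    expect_lt(d[r + 1] / d[1], 1e-10)
  }
})

test_that("with no tissue the stack energy sits on the vessel mask", {
  m <- vessel_plane_mask()
  sc <- simulate_ultrafast_stack(m, tissue_rank = 1, tissue_amp = 0,
                                 blood_amp = 1, noise_amp = 0, seed = 4)
  pw <- power_doppler(sc$stack)
  expect_equal(sum(pw[m]) / sum(pw), 1.0)
})

test_that("ultrafast scenes are reproducible and validate the mask", {
  m <- vessel_plane_mask()
  a <- simulate_ultrafast_stack(m, seed = 11)
  b <- simulate_ultrafast_stack(m, seed = 11)
  expect_identical(a$stack, b$stack)
  expect_error(
    simulate_ultrafast_stack(matrix(FALSE, 8, 8), blood_amp = 1),
    "empty"
  )
})

test_that("leading singular component carries >99% of tissue energy at
           tissue/blood ratio >= 100", {
  m <- vessel_plane_mask()
  sc <- simulate_ultrafast_stack(m, tissue_rank = 2, tissue_amp = 100,
                                 blood_amp = 1, seed = 3)
  d <- svd(matrix(sc$stack, 48 * 48, 300), nu = 0, nv = 0)$d
  expect_gt(d[1]^2 / sum(sc$tissue^2), 0.99)
})

# --- elevational blur ---------------------------------------------------------

test_that("elevational blur conserves flux, returns its kernel, and has
           an identity limit", {
  v <- array(0, c(9, 9, 21)); v[5, 5, 11] <- 10
  id <- apply_elevational_blur(v, 0)
  expect_identical(id$volume, v)
  bl <- apply_elevational_blur(v, 0.2, spacing_mm = 0.1)
  expect_equal(sum(bl$kernel), 1, tolerance = 1e-9)
  # impulse image equals the kernel along elevation
  prof <- bl$volume[5, 5, ]
  hw <- (length(bl$kernel) - 1) / 2
  expect_equal(prof[(11 - hw):(11 + hw)] / 10, bl$kernel, tolerance = 1e-9)
  expect_lt(abs(sum(bl$volume) - sum(v)) / sum(v), 0.001)
  expect_error(apply_elevational_blur(v, 10, spacing_mm = 0.1), "extent")
})

# --- histology fields ---------------------------------------------------------

test_that("histo fields carry exact ground truth and are reproducible", {
  f <- generate_histo_field(seed = 5, n_cd31_objects = 10,
                            pericyte_fraction = 0.4)
  expect_equal(f$truth$n_objects, 10)
  expect_equal(f$truth$coverage_pct, 40)
  expect_equal(sum(f$truth$objects$covered), 4)
  g <- generate_histo_field(seed = 5, n_cd31_objects = 10,
                            pericyte_fraction = 0.4)
  expect_identical(f$cd31, g$cd31)
  empty <- generate_histo_field(seed = 1, n_cd31_objects = 0)
  expect_true(is.na(empty$truth$coverage_pct))
  expect_error(
    generate_histo_field(seed = 1, n_cd31_objects = 500,
                         field_px = c(64, 64), radius_px = c(6, 9)),
    "disjointly"
  )
})
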