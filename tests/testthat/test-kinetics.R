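# --- SUV ----------------------------------------------------------------------

test_that("SUV normalization is definitional", {
  expect_equal(compute_suv(10000 / 30, 10, 30), 1.0)
  expect_equal(compute_suv(1000, 10, 30), 3.0)
  expect_equal(compute_suv(0, 10, 30), 0)
  expect_error(compute_suv(1, 0, 30), "dose")
  expect_error(compute_suv(1, 10, 0), "weight")
})

# --- tumor VOI ----------------------------------------------------------------

test_that("the 30% peak rule includes and excludes voxels at the cutoff", {
  suv <- array(0, c(10, 10, 10))
  suv[5, 5, 5] <- 10
  suv[5, 5, 6] <- 3.01
  suv[5, 5, 4] <- 2.99
  voi <- segment_tumor_voi(suv)
  expect_equal(voi$threshold, 3.0)
  expect_true(voi$mask[5, 5, 6])
  expect_false(voi$mask[5, 5, 4])
})

test_that("uniform volumes select the whole search region", {
  suv <- array(2, c(6, 6, 6))
  sr <- array(FALSE, c(6, 6, 6)); sr[2:5, 2:5, 2:5] <- TRUE
  voi <- segment_tumor_voi(suv, sr)
  expect_identical(voi$mask, sr)
  expect_error(segment_tumor_voi(array(0, c(4, 4, 4))), "peak")
})

test_that("only the peak-containing component is retained", {
  suv <- array(0, c(20, 10, 10))
  suv[3:6, 4:6, 4:6] <- 5      # cooler blob
  suv[14:17, 4:6, 4:6] <- 10   # hot blob with the peak
  voi <- segment_tumor_voi(suv)
  # oracle: the component containing the max, among voxels > 3
  cand <- suv > 3
  lab <- label_components(cand)
  oracle <- lab == lab[which.max(suv)]
  expect_identical(voi$mask, oracle)
  expect_false(any(voi$mask[3:6, , ]))
})

test_that("raising the VOI fraction never grows the VOI", {
  set.seed(31)
  suv <- vascumet:::gaussian_smooth(array(runif(27000), c(30, 30, 30)),
                                    c(2, 2, 2))
  prev <- NULL
  for (f in c(0.2, 0.3, 0.5, 0.7)) {
    m <- segment_tumor_voi(suv, fraction = f)$mask
    if (!is.null(prev)) expect_true(all(!m | prev))  # m subset of prev
    prev <- m
  }
})

# --- image-derived input function ----------------------------------------------

test_that("a constructed 5-voxel hot cluster is recovered exactly", {
  g <- vox_grid(c(12, 12, 12), 0.3)
  sched <- frame_schedule(rep(10, 8))
  nf <- 8
  dat <- array(1, c(12, 12, 12, nf))
  truth_tac <- seq(100, 30, length.out = nf)
  cl <- cbind(c(6, 7, 6, 6, 6), c(6, 6, 7, 6, 6), c(6, 6, 6, 7, 5))
  for (f in seq_len(nf))
    for (r in seq_len(5)) dat[cl[r, 1], cl[r, 2], cl[r, 3], f] <- truth_tac[f]
  dp <- dynamic_pet(dat, g, sched)
  mask <- array(TRUE, c(12, 12, 12))
  inp <- extract_input_function(dp, mask)
  expect_equal(inp$Cp, truth_tac, tolerance = 1e-12)
  expect_setequal(attr(inp, "cluster_voxels"),
                  cl[, 1] + 12 * (cl[, 2] - 1) + 144 * (cl[, 3] - 1))
})

test_that("flat volumes give the common TAC and small masks error", {
  g <- vox_grid(c(6, 6, 6), 0.3)
  sched <- frame_schedule(rep(10, 6))
  dat <- array(rep(c(5, 4, 3, 2, 1, 1), each = 216), c(6, 6, 6, 6))
  dp <- dynamic_pet(dat, g, sched)
  inp <- extract_input_function(dp, array(TRUE, c(6, 6, 6)))
  expect_equal(inp$Cp, c(5, 4, 3, 2, 1, 1))
  small <- array(FALSE, c(6, 6, 6)); small[1:4, 1, 1] <- TRUE
  expect_error(extract_input_function(dp, small), "fewer voxels")
})

# --- forward model -------------------------------------------------------------

test_that("the analytic 2TC solution matches an independent ODE integration", {
  tt <- seq(0, 3630, by = 2)
  inp <- simulate_plasma_input(tt)
  for (p in list(c(0.1, 0.2, 0.05), c(0.3, 0.05, 0.15), c(0.05, 0.6, 0.01))) {
    ct <- forward_2tc(list(K1 = p[1], k2 = p[2], k3 = p[3]), inp)
    sol <- ode_2tc(p[1], p[2], p[3], inp)
    expect_lt(max(abs(ct - sol)) / max(sol), 1e-4)
  }
})

test_that("degenerate forward-model limits hold", {
  tt <- seq(0, 600, by = 1)
  inp <- simulate_plasma_input(tt, peak_value = 8, mode = "constant")
  expect_true(all(forward_2tc(list(K1 = 0, k2 = 0.3, k3 = 0.1), inp) == 0))
  # k2 = 0: late slope (per minute) tends to K1 * Cp
  ct <- forward_2tc(list(K1 = 0.2, k2 = 0, k3 = 0.07), inp)
  slope <- (ct[length(tt)] - ct[length(tt) - 60]) / 1  # per 60 s = per min
  expect_equal(slope, 0.2 * 8, tolerance = 1e-6)
  expect_error(forward_2tc(list(K1 = 0.1, k2 = -0.1, k3 = 0), inp),
               "non-negative")
})

# --- fitting and Patlak ---------------------------------------------------------

test_that("noiseless TACs are recovered within 1% from any admissible start", {
  tt <- seq(0, 3630, by = 2)
  inp <- simulate_plasma_input(tt)
  sched <- petrus_schedule()
  truth <- c(K1 = 0.1, k2 = 0.2, k3 = 0.05)
  tac <- frame_average(tt, forward_2tc(as.list(truth), inp), sched)
  for (st in list(c(0.1, 0.1, 0.05), c(0.8, 0.8, 0.8), c(0.01, 0.5, 0.3))) {
    fit <- fit_2tc(tac, inp, sched, init = st)
    expect_lt(max(abs(c(fit$K1, fit$k2, fit$k3) - truth) / truth), 0.01)
  }
})

test_that("an all-zero TAC drives K1 to zero", {
  tt <- seq(0, 3630, by = 5)
  inp <- simulate_plasma_input(tt)
  sched <- petrus_schedule()
  fit <- fit_2tc(rep(0, 31), inp, sched)
  expect_lt(fit$K1, 1e-4)
})

test_that("median Ki bias stays below 5% under 5% noise (Monte Carlo)", {
  tt <- seq(0, 3630, by = 5)
  inp <- simulate_plasma_input(tt)
  sched <- petrus_schedule()
  truth <- list(K1 = 0.1, k2 = 0.2, k3 = 0.05)
  tac0 <- frame_average(tt, forward_2tc(truth, inp), sched)
  ki_true <- ki_from_rates(0.1, 0.2, 0.05)
  set.seed(99)
  kis <- replicate(60, {
    tac <- tac0 * (1 + 0.05 * rnorm(length(tac0)))
    fit_2tc(pmax(tac, 0), inp, sched)$Ki
  })
  expect_lt(abs(median(kis) - ki_true) / ki_true, 0.05)
})

test_that("Patlak is exact for pure trapping under constant input", {
  sched <- petrus_schedule()
  tt <- seq(0, 3630, by = 1)
  inp <- simulate_plasma_input(tt, peak_value = 5, mode = "constant")
  ki <- 0.03 # per minute
  mids <- frame_midpoints(sched)
  tac <- ki * 5 * mids / 60
  pk <- patlak(tac, inp, sched, t_star_s = 600)
  expect_equal(pk$Ki, ki, tolerance = 1e-9)
  expect_equal(pk$intercept, 0, tolerance = 1e-9)
})

test_that("Patlak slope matches Ki = K1 k3/(k2+k3) past the transient", {
  tt <- seq(0, 3630, by = 2)
  inp <- simulate_plasma_input(tt)
  sched <- petrus_schedule()
  tac <- frame_average(tt, forward_2tc(list(K1 = 0.1, k2 = 0.2, k3 = 0.05),
                                       inp), sched)
  pk <- patlak(tac, inp, sched, t_star_s = 600)
  expect_equal(pk$Ki, 0.02, tolerance = 0.02)
  # no trapping: slope ~ 0
  tac0 <- frame_average(tt, forward_2tc(list(K1 = 0.1, k2 = 0.2, k3 = 0),
                                        inp), sched)
  pk0 <- patlak(tac0, inp, sched, t_star_s = 600)
  expect_lt(abs(pk0$Ki), 1e-4)
})

# --- derived quantities ---------------------------------------------------------

test_that("Ki and MRGlu formulas are exact", {
  expect_equal(ki_from_rates(0.1, 0.1, 0.1), 0.05)
  expect_equal(ki_from_rates(0.1, 0.3, 0), 0)
  expect_equal(ki_from_rates(0.1, 0, 0.2), 0.1)
  expect_error(ki_from_rates(0.1, 0, 0), "undefined")
  expect_equal(mrglu(0.069, 10), 1.0)
  expect_equal(mrglu(0, 10), 0)
  expect_equal(mrglu(0.05, 2, LC = 1), 0.1)
  expect_error(mrglu(0.1, 5, LC = 0), "LC")
  # kinetic_params derives both and defaults LC to 0.69
  kp <- kinetic_params(0.1, 0.2, 0.05, PG = 6.9)
  expect_equal(kp$LC, 0.69)
  expect_equal(kp$MRGlu, 0.02 * 6.9 / 0.69)
})

test_that("TLG equals the voxelwise sum times voxel volume and is additive", {
  set.seed(12)
  suv <- array(runif(8000, 0, 4), c(20, 20, 20))
  voi <- array(runif(8000) < 0.3, c(20, 20, 20))
  voi[1] <- TRUE
  vml <- 0.001
  expect_equal(tlg(suv, voi, vml), sum(suv[voi]) * vml)
  # mean SUV x volume formulation
  expect_equal(tlg(suv, voi, vml), mean(suv[voi]) * sum(voi) * vml)
  # additivity over a partition
  part <- array(sample(1:3, 8000, TRUE), c(20, 20, 20))
  total <- sum(sapply(1:3, function(k) {
    sub <- voi & part == k
    if (any(sub)) tlg(suv, sub, vml) else 0
  }))
  expect_equal(total, tlg(suv, voi, vml))
  expect_error(tlg(suv, array(FALSE, c(20, 20, 20)), vml), "empty")
})

test_that("caliper volume formula and enrollment boundary are exact", {
  cv <- caliper_volume(10, 5)
  expect_equal(cv$volume_mm3, 125)
  expect_false(cv$enrolled)
  cv2 <- caliper_volume(11.2, 5)
  expect_equal(cv2$volume_mm3, 140)
  expect_true(cv2$enrolled)   # inclusive boundary
  expect_error(caliper_volume(10, 0), "width")
  expect_error(caliper_volume(5, 10), "swapped")
})
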