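make_table <- function(values_fun, n = 8, weeks = c(0, 1, 6),
                       pars = c("a", "b"), group = "SUNI") {
  g <- expand.grid(subject = paste0("m", seq_len(n)), week = weeks,
                   parameter = pars, stringsAsFactors = FALSE)
  g$group <- group
  g$value <- values_fun(nrow(g), g)
  build_cohort_table(g[c("subject", "group", "week", "parameter", "value")])
}

test_that("cohort tables merge tidily and reject duplicates", {
  tb <- make_table(function(n, g) seq_len(n))
  expect_equal(nrow(tb), 8 * 3 * 2)
  expect_s3_class(tb, "cohort_table")
  expect_equal(nrow(build_cohort_table(list())), 0)
  dup <- as.data.frame(tb[c(1, 1), ])
  expect_error(build_cohort_table(dup), "duplicate")
})

test_that("baseline normalization maps W0 to 1 and excludes zero baselines", {
  tb <- make_table(function(n, g) 2^g$week, weeks = c(0, 1, 2, 3))
  nn <- normalize_to_baseline(tb, "a")
  for (w in c(0, 1, 2, 3))
    expect_true(all(nn$value[nn$week == w] == 2^w))
  # constant series -> all 1
  tc <- make_table(function(n, g) rep(3, n))
  expect_true(all(normalize_to_baseline(tc, "a")$value == 1))
  # missing baseline subject excluded with warning
  tb2 <- as.data.frame(tb)
  tb2 <- tb2[!(tb2$subject == "m1" & tb2$week == 0), ]
  expect_warning(out <- normalize_to_baseline(build_cohort_table(tb2), "a"),
                 "m1")
  expect_false("m1" %in% out$subject)
})

test_that("a delta constructed as an exact multiple of the endpoint gives
           R^2 = 1", {
  n <- 10
  set.seed(8)
  endpoint <- rnorm(n)
  g <- expand.grid(subject = paste0("m", 1:n), week = c(0, 1, 6),
                   parameter = "a", stringsAsFactors = FALSE)
  g$group <- "SUNI"
  g$value <- NA_real_
  g$value[g$week == 0] <- 0
  g$value[g$week == 1] <- 2 * endpoint   # delta = 2 x endpoint
  g$value[g$week == 6] <- endpoint
  hm <- delta_endpoint_correlation(build_cohort_table(g))
  expect_equal(unname(hm$r2["a", "a"]), 1.0, tolerance = 1e-12)
})

test_that("independent null cohorts have mean R^2 near 1/(n-1)", {
  n <- 12
  set.seed(17)
  r2s <- replicate(800, {
    dx <- rnorm(n); y <- rnorm(n)
    cor(dx, y)^2
  })
  expect_equal(mean(r2s), 1 / (n - 1), tolerance = 0.015)
  # and the package's heatmap reproduces that behavior cell-wise
  vals <- unlist(lapply(1:150, function(s) {
    hm <- delta_endpoint_correlation(simulate_null_cohort(seed = s))
    hm$r2
  }))
  expect_lt(abs(mean(vals) - 1 / (n - 1)), 0.015)
})

test_that("zero-variance endpoints are undefined, not zero", {
  n <- 8
  g <- expand.grid(subject = paste0("m", 1:n), week = c(0, 1, 6),
                   parameter = "a", stringsAsFactors = FALSE)
  g$group <- "VEH"
  g$value <- rnorm(nrow(g))
  g$value[g$week == 6] <- 5  # constant endpoint
  hm <- delta_endpoint_correlation(build_cohort_table(g))
  expect_true(hm$undefined["a", "a"])
  expect_true(is.na(hm$r2["a", "a"]))
})

test_that("fixed and analytic significance rules behave as stated", {
  hm <- delta_endpoint_correlation(simulate_null_cohort(seed = 23))
  hm$r2[1, 1] <- 0.62; hm$r2[1, 2] <- 0.60  # plant values near the fixed cut
  msk <- significance_mask(hm)
  expect_true(msk$fixed[1, 1])
  expect_false(msk$fixed[1, 2])
  # alpha = 1 makes everything significant in the analytic mask
  all_ <- significance_mask(hm, alpha = 1)
  expect_true(all(all_$analytic[!hm$undefined]))
  # analytic critical value matches the permutation/simulation null quantile
  set.seed(5)
  null_r2 <- replicate(4000, cor(rnorm(12), rnorm(12))^2)
  emp <- unname(quantile(null_r2, 0.99))
  expect_equal(critical_r2(12, 0.01), emp, tolerance = 0.04)
  expect_error(critical_r2(2, 0.01), "n >= 3")
})

test_that("the fixed 0.61 cut and the analytic n=12 cut differ (both kept)", {
  expect_false(isTRUE(all.equal(critical_r2(12, 0.01), 0.61,
                                tolerance = 0.01)))
  hm <- delta_endpoint_correlation(simulate_null_cohort(seed = 2))
  msk <- significance_mask(hm)
  expect_true(is.matrix(msk$fixed) && is.matrix(msk$analytic))
})

test_that("group comparison: identical groups give adjusted p = 1", {
  set.seed(3)
  base <- expand.grid(subject = paste0("m", 1:8), week = 0:3,
                      parameter = "a", stringsAsFactors = FALSE)
  base$value <- rnorm(nrow(base))
  a <- base; a$group <- "SUNI"
  b <- base; b$subject <- sub("m", "v", b$subject); b$group <- "VEH"
  b$value <- a$value  # identical distributions
  tb <- build_cohort_table(rbind(a, b)[c("subject", "group", "week",
                                         "parameter", "value")])
  gc <- group_compare(tb, "a")
  expect_true(all(gc$per_week$p_adj == 1))
  expect_error(group_compare(build_cohort_table(a[c("subject", "group",
                                                    "week", "parameter",
                                                    "value")]), "a"),
               "both groups")
})

test_that("widely separated groups are significant at every week, and
           Bonferroni is definitional", {
  set.seed(7)
  g <- expand.grid(subject = paste0("m", 1:16), week = 0:3,
                   parameter = "a", stringsAsFactors = FALSE)
  g$group <- ifelse(as.integer(sub("m", "", g$subject)) <= 8, "SUNI", "VEH")
  g$value <- rnorm(nrow(g)) + ifelse(g$group == "SUNI", 10, 0)
  tb <- build_cohort_table(g[c("subject", "group", "week", "parameter",
                               "value")])
  gc <- group_compare(tb, "a")
  expect_true(all(gc$per_week$p_adj < 0.05))
  m <- nrow(gc$per_week)
  expect_equal(gc$per_week$p_adj, pmin(1, m * gc$per_week$p_raw))
  gw <- group_compare(tb, "a", test = "wilcoxon")
  expect_true(all(gw$per_week$p_adj < 0.05))
})

test_that("heatmap cells are invariant to affine rescaling of parameters", {
  tb <- simulate_null_cohort(seed = 31)
  hm1 <- delta_endpoint_correlation(tb)
  tb2 <- tb
  tb2$value[tb2$parameter == "mrglu"] <- 100 * tb2$value[tb2$parameter ==
                                                           "mrglu"] - 3
  hm2 <- delta_endpoint_correlation(tb2)
  expect_equal(hm1$r2, hm2$r2, tolerance = 1e-9)
})
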