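test_that("histograms are normalized to percent of contributing pixels", {
  h <- build_histogram(c(2.05, 2.01, 2.3, 2.49), bin_width = 0.5)
  expect_equal(sum(h$counts_pct), 100)
  expect_equal(max(h$counts_pct), 100)  # all four values in one bin
  h2 <- build_histogram(c(1, 1, 2, 3), bin_width = 1, range = c(1, 4))
  expect_equal(h2$counts_pct, c(50, 25, 25))
  expect_equal(h2$breaks, 1:4)
  set.seed(1)
  for (i in 1:5) {
    h3 <- build_histogram(rnorm(500, 10, 2), bin_width = 0.1)
    expect_equal(sum(h3$counts_pct), 100, tolerance = 1e-6)
  }
  expect_error(build_histogram(numeric(0)), "no values")
  expect_error(build_histogram(c(1, 2), bin_width = 0), "bin_width")
  expect_error(build_histogram(c(1, 5), bin_width = 1, range = c(1, 3)),
               "cover")
})

test_that("median and IQR use linear-interpolation quantiles", {
  expect_equal(median_iqr(1:5), c(median = 3, iqr = 2))
  expect_equal(median_iqr(c(4, 4, 4)), c(median = 4, iqr = 0))
  # type-7 quantiles: Q25 = 1.75, Q75 = 3.25
  expect_equal(median_iqr(1:4), c(median = 2.5, iqr = 1.5))
  expect_error(median_iqr(numeric(0)), "no finite")
})

test_that("bootstrap confidence limits are seeded and degenerate-safe", {
  expect_equal(bootstrap_cl(rep(5, 8), seed = 1),
               c(lower = 5, upper = 5))
  x <- c(3.1, 4.5, 2.8, 5.0, 3.9, 4.1, 3.3, 4.8, 3.6, 4.2)
  a <- bootstrap_cl(x, seed = 7)
  b <- bootstrap_cl(x, seed = 7)
  expect_identical(a, b)
  expect_lt(a[["lower"]], a[["upper"]])
  expect_gt(a[["lower"]], min(x))
  expect_lt(a[["upper"]], max(x))
  expect_error(bootstrap_cl(3), "at least 2")
})

test_that("confidence-limit flagging is inclusive at the bounds", {
  cl <- c(2, 4)
  expect_false(flag_outside_cl(2, cl))
  expect_false(flag_outside_cl(4, cl))
  expect_false(flag_outside_cl(3, cl))
  expect_true(flag_outside_cl(4.01, cl))
  expect_true(flag_outside_cl(1.99, cl))
})

test_that("control cutoff is the pooled linear-interpolation upper quartile", {
  expect_equal(control_cutoff(1:4, min_n = 4), 3.25)
  expect_equal(control_cutoff(rep(2, 200)), 2)
  set.seed(42)
  u <- runif(1e5)
  expect_equal(control_cutoff(u), 0.75, tolerance = 0.01)
  expect_error(control_cutoff(1:10), "100")
})

test_that("injury index counts pixels strictly beyond the cutoff", {
  expect_equal(injury_index(c(5, 6, 7), 4), 100)
  expect_equal(injury_index(1:10, 7.5), 30)
  expect_equal(injury_index(1:10, 10), 0)
  expect_error(injury_index(NA_real_, 1), "no valid")
})

test_that("control-like samples give ~25% injury in expectation", {
  set.seed(11)
  cutoff <- control_cutoff(rlnorm(2e5, 2, 0.5))
  idx <- replicate(60, injury_index(rlnorm(5000, 2, 0.5), cutoff))
  expect_equal(mean(idx), 25, tolerance = 2)
})

test_that("injury index is monotone in upward shifts of the treated distribution", {
  set.seed(3)
  v <- rlnorm(5000, 2, 0.4)
  cutoff <- control_cutoff(v)
  idx <- vapply(c(0, 0.5, 1, 2, 4),
                function(d) injury_index(v + d, cutoff), numeric(1))
  expect_true(all(diff(idx) >= 0))
})

test_that("rank-sum test: exact enumeration for small samples, symmetric", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$U, 0)
  expect_equal(rs$p, 0.1)  # 2 / choose(6, 3)
  same <- rank_sum_test(c(1.2, 3.4, 2.2, 5.1), c(1.2, 3.4, 2.2, 5.1))
  expect_equal(same$p, 1, tolerance = 1e-6)
  a <- rnorm(15); b <- rnorm(15, 1)
  expect_equal(rank_sum_test(a, b)$p, rank_sum_test(b, a)$p)
  expect_error(rank_sum_test(1, c(2, 3)), "at least 2")
})

test_that("group summaries report SEM over animals", {
  vals <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  gs <- group_summary(vals)
  expect_equal(unname(gs$medians), c(2, 3, 4))
  expect_equal(gs$mean_median, 3)
  expect_equal(gs$sem_median, sd(c(2, 3, 4)) / sqrt(3))
  expect_true(all(gs$iqrs >= 0))
})

test_that("control reference assembles cutoffs and confidence limits", {
  set.seed(5)
  control <- list(
    capillary = list(
      offset = lapply(1:6, function(i) rnorm(300, 10 + i / 10, 2))
    )
  )
  ref <- build_control_reference(control, site = "retina", seed = 2)
  expect_s3_class(ref, "control_reference")
  expect_equal(ref$class, "capillary")
  expect_lte(ref$cl_low, ref$cl_high)
  expect_true(is.finite(ref$cutoff))
  td <- withr::local_tempdir()
  p <- write_reference(ref, file.path(td, "ref.json"))
  ref2 <- read_reference(p)
  expect_equal(ref2$cutoff, ref$cutoff)
  expect_equal(ref2$cl_low, ref$cl_low)
})
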