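# Construct a minimal dynamics_maps object directly (unit-test scaffold).
toy_maps <- function(half_rise, reason = NULL) {
  codes <- reason_codes()
  if (is.null(reason))
    reason <- matrix(ifelse(is.finite(half_rise), codes[["ok"]],
                            codes[["background"]]),
                     nrow(half_rise), ncol(half_rise))
  structure(list(half_rise = half_rise, half_fall = half_rise + 4,
                 offset = half_rise * 0 + 10, reason = reason,
                 config = analysis_config()),
            class = "dynamics_maps")
}

test_that("segmentation recovers the synthetic vessel tree (Dice >= 0.8)", {
  cfg <- scene_config("retina", size = 64, seed = 5)
  sim <- render_video(cfg, analytic_truth = FALSE)
  vm <- segment_vessels(peak_image(sim$stack))
  gtv <- sim$truth$labels %in% 1:2
  dice <- 2 * sum(vm & gtv) / (sum(vm) + sum(gtv))
  expect_gte(dice, 0.8)
  expect_type(vm, "logical")
})

test_that("segmented components are 8-connected and at least 20 px", {
  cfg <- scene_config("retina", size = 64, seed = 5)
  sim <- render_video(cfg, analytic_truth = FALSE)
  vm <- segment_vessels(peak_image(sim$stack))
  lab4 <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(vm * 1))),
                 nrow(vm), ncol(vm))
  lab8 <- angiodyn:::merge_diagonal_labels(lab4)
  sizes <- tabulate(lab8[lab8 > 0])
  expect_true(all(sizes[sizes > 0] >= 20))
})

test_that("uniform peak images cannot be segmented", {
  expect_error(segment_vessels(matrix(3, 16, 16)), "uniform")
})

test_that("diagonally touching components merge into one 8-connected component", {
  m <- matrix(0L, 6, 6)
  m[cbind(1:4, 1:4)] <- 1L   # pure diagonal line: 4 components 4-connected
  lab4 <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(m))), 6, 6)
  expect_gt(max(lab4), 1)
  lab8 <- angiodyn:::merge_diagonal_labels(lab4)
  expect_equal(max(lab8), 1)
})

test_that("fill-timing classification reaches 95% accuracy on synthetic retina", {
  # arterial and venous arrival times ~N(5.5, 0.2^2) and N(6.5, 0.2^2)
  classes <- default_scene_classes("retina")
  classes$artery$t0_mean <- 5.5; classes$artery$t0_sd <- 0.2
  classes$vein$t0_mean <- 6.5; classes$vein$t0_sd <- 0.2
  classes$capillary$t0_mean <- 6.0
  cfg <- scene_config("retina", size = 64, classes = classes, seed = 5)
  sim <- render_video(cfg, analytic_truth = FALSE)
  maps <- compute_maps(sim$stack,
                       config = analysis_config(saturation_value = 255))
  vm <- segment_vessels(peak_image(sim$stack))
  cl <- classify_by_timing(maps, vm)
  pred <- cl$labels; gt <- sim$truth$labels
  on_vessel <- pred %in% 1:2 & gt %in% 1:2
  acc <- mean(pred[on_vessel] == gt[on_vessel])
  expect_gte(acc, 0.95)
  # class invariant: artery fills before capillary before vein
  med <- vapply(1:3, function(L) median(maps$half_rise[pred == L], na.rm = TRUE),
                numeric(1))
  expect_lte(med[1], med[3])
  expect_lte(med[3], med[2])
  expect_equal(sum(cl$counts), sum(pred != 0))
  expect_gt(cl$quality, 0.3)
})

test_that("two vessel pixels split into early artery and late vein", {
  hr <- matrix(NA_real_, 4, 4)
  hr[1, 1] <- 5.0; hr[1, 2] <- 5.1; hr[4, 4] <- 7.0; hr[4, 3] <- 6.9
  maps <- toy_maps(hr)
  vm <- is.finite(hr)
  cl <- classify_by_timing(maps, vm)
  expect_equal(cl$labels[1, 1], 1L)
  expect_equal(cl$labels[1, 2], 1L)
  expect_equal(cl$labels[4, 4], 2L)
  expect_equal(cl$labels[4, 3], 2L)
})

test_that("degenerate timing distributions are rejected", {
  hr <- matrix(NA_real_, 4, 4); hr[1, 1:4] <- 6.0
  expect_error(classify_by_timing(toy_maps(hr), is.finite(hr)), "identical")
  # too few valid vessel pixels
  hr2 <- matrix(NA_real_, 4, 4); hr2[1, 1] <- 5
  vm2 <- matrix(TRUE, 4, 4)
  expect_error(classify_by_timing(toy_maps(hr2), vm2), "50%")
})

test_that("classification is stable under consistent relabeling of pixels", {
  set.seed(8)
  hr <- matrix(NA_real_, 8, 8)
  hr[1:4, ] <- rnorm(32, 5.5, 0.15)
  hr[5:8, ] <- rnorm(32, 6.8, 0.15)
  vm <- is.finite(hr)
  a <- classify_by_timing(toy_maps(hr), vm)
  b <- classify_by_timing(toy_maps(t(hr)), t(vm))
  expect_identical(a$labels, t(b$labels))
  expect_identical(a$counts, b$counts)
})

test_that("manual label maps take precedence as first-class input", {
  lab <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  mc <- manual_classification(lab)
  expect_equal(mc$method, "manual")
  expect_equal(sum(mc$counts), sum(lab != 0))
})
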