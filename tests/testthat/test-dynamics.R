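test_that("normalization maps baseline to 0 and peak to exactly 100", {
  tt <- seq(-5, 55, by = 1 / 30)
  raw <- ifelse(tt < 0, 10, 10 + 100 * pmax(0, 1 - abs(tt - 10) / 10))
  nc <- normalize_curve(raw, tt)
  expect_equal(nc$baseline_mean, 10)
  expect_equal(max(nc$values), 100)
  expect_equal(nc$values[which.max(nc$values)], 100)
  expect_equal(nc$peak_time, 10, tolerance = 1 / 30)
  expect_equal(mean(nc$values[tt < 0]), 0, tolerance = 1e-9)
})

test_that("constant curves yield no_peak and valid-curve operations refuse them", {
  tt <- seq(-5, 20, by = 0.1)
  nc <- normalize_curve(rep(7, length(tt)), tt)
  expect_equal(nc$reason, "no_peak")
  expect_error(compute_half_rise(nc), "not valid")
  expect_error(compute_half_fall(nc), "not valid")
})

test_that("adding a constant pseudofluorescence leaves normalized values unchanged", {
  tt <- seq(-5, 55, by = 1 / 30)
  p <- curve_params(t0 = 4, alpha = 3, beta = 1.5, amplitude = 80,
                    baseline = 20)
  raw <- simulate_pixel_curve(p, tt)
  a <- normalize_curve(raw, tt)
  b <- normalize_curve(raw + 50, tt)
  expect_equal(a$values, b$values)
  expect_equal(a$raw_values, b$raw_values)
})

test_that("amplitude scaling leaves all three indices unchanged", {
  tt <- seq(-5, 55, by = 1 / 30)
  p <- curve_params(t0 = 5, alpha = 3, beta = 1.2, amplitude = 90,
                    leak_frac = 0.2, baseline = 0)
  raw <- simulate_pixel_curve(p, tt)
  for (k in c(0.5, 3.7)) {
    a <- normalize_curve(raw, tt); b <- normalize_curve(raw * k, tt)
    expect_equal(compute_half_rise(a), compute_half_rise(b))
    expect_equal(as.numeric(compute_half_fall(a)),
                 as.numeric(compute_half_fall(b)))
    expect_equal(compute_offset(a, c(50, 55)), compute_offset(b, c(50, 55)))
  }
})

test_that("half-rise of a linear ramp crosses at the midpoint", {
  tt <- seq(-2, 12, by = 0.1)
  raw <- ifelse(tt < 0, 0, pmin(tt * 10, 100))
  nc <- normalize_curve(raw, tt)
  expect_equal(compute_half_rise(nc), 5.0, tolerance = 1e-9)
})

test_that("half-rise interpolates linearly between the bracketing samples", {
  # 30 fps samples: 40% at t = 5.0000, 60% at t = 5.0333 -> crossing 5.0167
  tt <- seq(-1, 10, by = 1 / 30)
  v <- numeric(length(tt))
  ramp <- tt >= 0
  i40 <- which.min(abs(tt - 5))
  v[ramp] <- approx(c(0, tt[i40], tt[i40 + 1], 8, 10),
                    c(0, 40, 60, 100, 100), xout = tt[ramp])$y
  nc <- normalize_curve(v, tt)
  expect_equal(compute_half_rise(nc), tt[i40] + 0.5 / 30, tolerance = 1e-6)
})

test_that("half-fall of a triangular curve and censoring of plateaus", {
  tt <- seq(-2, 25, by = 0.05)
  tri <- ifelse(tt < 0, 0, ifelse(tt <= 10, 10 * tt,
                                  pmax(0, 100 - 10 * (tt - 10))))
  nc <- normalize_curve(tri, tt)
  expect_equal(as.numeric(compute_half_fall(nc)), 15.0, tolerance = 1e-9)
  plateau <- ifelse(tt < 0, 0, ifelse(tt <= 10, 10 * tt,
                                      pmax(60, 100 - 10 * (tt - 10))))
  ncp <- normalize_curve(plateau, tt)
  hf <- compute_half_fall(ncp)
  expect_true(is.na(hf))
  expect_true(attr(hf, "censored"))
})

test_that("offset equals the settled plateau and clamps at baseline return", {
  tt <- seq(-5, 55, by = 1 / 30)
  raw <- ifelse(tt < 0, 0, ifelse(tt < 5, 20 * tt, pmax(20, 100 - 10 * (tt - 5))))
  nc <- normalize_curve(raw, tt)
  expect_equal(compute_offset(nc, c(50, 55)), 20.0, tolerance = 1e-9)
  raw0 <- ifelse(tt >= 0 & tt < 10, 100 * sin(pi * tt / 10)^2, 0)
  nc0 <- normalize_curve(raw0, tt)
  expect_equal(compute_offset(nc0, c(50, 55)), 0.0)
  expect_error(compute_offset(nc, c(nc$peak_time - 1, 55)), "after the peak")
})

test_that("pipeline indices match the 1 ms fine-grid oracle on gamma-variate curves", {
  cases <- list(list(t0 = 4, alpha = 3, beta = 1.5, leak_frac = 0),
                list(t0 = 5.5, alpha = 3, beta = 1.0, leak_frac = 0.15))
  for (cs in cases) {
    p <- do.call(curve_params, c(cs, list(amplitude = 100, tau_leak = 10)))
    sc <- sampled_curve(p)
    nc <- normalize_curve(sc$raw, sc$times)
    o <- do.call(oracle_dynamics, c(cs, list(amplitude = 100, tau_leak = 10)))
    expect_equal(compute_half_rise(nc), o$half_rise, tolerance = 1 / 60)
    expect_equal(as.numeric(compute_half_fall(nc)), o$half_fall,
                 tolerance = 1 / 60)
    expect_equal(compute_offset(nc, c(50, 55)), o$offset, tolerance = 1)
  }
})

test_that("a slowly saturating leak of 0.4 yields an offset of 40 over a long recording", {
  # leak time constant much slower than transit, recording much longer
  # than the leak time constant, so plateau/peak -> leak_frac
  p <- curve_params(t0 = 4, alpha = 3, beta = 1, amplitude = 100,
                    leak_frac = 0.4, tau_leak = 60)
  tt <- seq(-5, 600, by = 0.2)
  raw <- simulate_pixel_curve(p, tt)
  nc <- normalize_curve(raw, tt)
  expect_equal(compute_offset(nc, c(550, 600)), 40, tolerance = 1)
})

test_that("delaying a curve shifts half-rise and half-fall by exactly the delay", {
  tt <- seq(-5, 55, by = 1 / 30)
  p <- curve_params(t0 = 5, alpha = 3, beta = 1.2, amplitude = 100,
                    leak_frac = 0)
  raw <- simulate_pixel_curve(p, tt)
  k <- 45  # 1.5 s in samples
  delayed <- c(rep(0, k), raw[seq_len(length(raw) - k)])
  a <- normalize_curve(raw, tt); b <- normalize_curve(delayed, tt)
  expect_equal(compute_half_rise(b) - compute_half_rise(a), 1.5,
               tolerance = 1e-9)
  expect_equal(as.numeric(compute_half_fall(b)) - as.numeric(compute_half_fall(a)),
               1.5, tolerance = 1e-9)
  expect_equal(compute_offset(b, c(50, 55)), compute_offset(a, c(50, 55)),
               tolerance = 0.05)
})

test_that("computed offset is monotone in the leak fraction", {
  tt <- seq(-5, 55, by = 1 / 30)
  offs <- vapply(c(0, 0.1, 0.2, 0.35, 0.5), function(lf) {
    p <- curve_params(t0 = 5, alpha = 3, beta = 1, amplitude = 100,
                      leak_frac = lf)
    compute_offset(normalize_curve(simulate_pixel_curve(p, tt), tt), c(50, 55))
  }, numeric(1))
  expect_true(all(diff(offs) > 0))
})

test_that("saturated samples set the saturation flag", {
  tt <- seq(-5, 55, by = 1 / 30)
  p <- curve_params(t0 = 5, alpha = 3, beta = 1, amplitude = 300)
  raw <- pmin(simulate_pixel_curve(p, tt), 255)
  nc <- normalize_curve(raw, tt, saturation_value = 255)
  expect_true(nc$saturated)
  expect_equal(nc$reason, "ok")
})

test_that("noiseless synthetic maps reproduce analytic ground truth", {
  cfg <- scene_config("retina", size = 32, noise_sigma = 0, noise_prop = 0,
                      motion_amplitude = 0, bit_depth = NA, seed = 3)
  sim <- render_video(cfg)
  maps <- compute_maps(sim$stack, mask = sim$truth$labels)
  gt <- sim$truth$dynamics
  codes <- reason_codes()
  ok <- maps$reason %in% c(codes[["ok"]], codes[["censored_half_fall"]])
  fg <- sim$truth$labels != 0
  expect_true(all(ok[fg]))
  expect_lt(max(abs(maps$half_rise[fg] - gt$half_rise[fg])), 1 / 30)
  both <- fg & is.finite(maps$half_fall) & is.finite(gt$half_fall)
  expect_gt(sum(both), 100)
  expect_lt(max(abs(maps$half_fall[both] - gt$half_fall[both])), 1 / 30)
  expect_lt(max(abs(maps$offset[fg] - gt$offset[fg])), 1)
})

test_that("an all-baseline stack flags every pixel as signal-free", {
  fr <- array(5, c(60, 8, 8))
  st <- video_stack(fr, frame_rate = 4, bolus_onset_s = 5)
  maps <- compute_maps(st)
  expect_true(all(maps$reason == reason_codes()[["no_peak"]]))
  expect_true(all(is.na(maps$half_rise)))
})

test_that("maps are reproducible bit-exactly across runs", {
  cfg <- tiny_scene(seed = 21)
  sim <- render_video(cfg, analytic_truth = FALSE)
  a <- compute_maps(sim$stack, mask = sim$truth$labels)
  b <- compute_maps(sim$stack, mask = sim$truth$labels)
  expect_identical(a, b)
})

test_that("half-rise is below half-fall wherever both are valid", {
  cfg <- tiny_scene(seed = 30)
  sim <- render_video(cfg, analytic_truth = FALSE)
  maps <- compute_maps(sim$stack, mask = sim$truth$labels)
  both <- is.finite(maps$half_rise) & is.finite(maps$half_fall)
  expect_gt(sum(both), 50)
  expect_true(all(maps$half_rise[both] < maps$half_fall[both]))
  valid <- is.finite(maps$offset)
  expect_true(all(maps$offset[valid] >= 0 & maps$offset[valid] <= 100))
})
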