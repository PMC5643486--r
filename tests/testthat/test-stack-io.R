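make_stack <- function(n_frames = 40, n = 8, frame_rate = 4, bolus = 5,
                       int8 = TRUE) {
  set.seed(99)
  fr <- array(runif(n_frames * n * n, 0, 255), c(n_frames, n, n))
  if (int8) fr <- round(fr)
  video_stack(fr, frame_rate = frame_rate, bolus_onset_s = bolus,
              animal_id = "a1", site = "retina", saturation_value = 255)
}

test_that("a 30 fps one-minute stack spans 60 s with a baseline segment", {
  fr <- array(1, c(1800, 4, 4))
  fr[1000, 2, 2] <- 2  # some post-bolus signal
  st <- video_stack(fr, frame_rate = 30, bolus_onset_s = 5)
  d <- dim(st$frames)
  expect_equal(d[1] / st$frame_rate, 60)
  expect_gt(d[1], st$frame_rate * st$bolus_onset_s)
  expect_equal(sum(frame_times(st) < 5), 150)
})

test_that("stacks without post-bolus frames are rejected", {
  fr <- array(1, c(1, 8, 8))
  expect_error(video_stack(fr, 30, 5), "post-bolus")
  expect_error(video_stack(array(-1, c(40, 4, 4)), 4, 5), "non-negative")
})

test_that("stack write/read round-trips intensities bit-exactly", {
  st <- make_stack()
  td <- withr::local_tempdir()
  vp <- file.path(td, "v.tif"); mp <- file.path(td, "v.json")
  write_stack(st, vp, mp)
  st2 <- read_stack(vp, mp)
  expect_identical(st2$frames, st$frames)
  expect_equal(st2$frame_rate, st$frame_rate)
  expect_equal(st2$bolus_onset_s, st$bolus_onset_s)
  expect_equal(st2$animal_id, "a1")
  expect_equal(st2$saturation_value, 255)
})

test_that("readers reject missing metadata and truncated stacks", {
  st <- make_stack(n_frames = 10, bolus = 1)
  td <- withr::local_tempdir()
  vp <- file.path(td, "v.tif"); mp <- file.path(td, "v.json")
  meta <- write_stack(st, vp, mp)
  bad <- meta; bad$frame_rate <- NULL
  jsonlite::write_json(bad, mp, auto_unbox = TRUE, null = "null")
  expect_error(read_stack(vp, mp), "frame_rate")
  bad2 <- meta; bad2$n_frames <- 12
  jsonlite::write_json(bad2, mp, auto_unbox = TRUE, null = "null")
  expect_error(read_stack(vp, mp), "truncated")
})

test_that("stacks with inconsistent page sizes are rejected", {
  td <- withr::local_tempdir()
  vp <- file.path(td, "bad.tif"); mp <- file.path(td, "bad.json")
  suppressWarnings(tiff::writeTIFF(list(matrix(0.5, 8, 8), matrix(0.5, 4, 4)), vp))
  jsonlite::write_json(list(frame_rate = 4, bolus_onset_s = 0.5), mp,
                       auto_unbox = TRUE)
  expect_error(read_stack(vp, mp), "size differs")
})

test_that("label maps round-trip and out-of-range values error", {
  lab <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  td <- withr::local_tempdir()
  p <- file.path(td, "lab.tif")
  write_label_map(lab, p)
  expect_identical(read_label_map(p), lab)
  p2 <- file.path(td, "lab.png")
  write_label_map(lab, p2)
  expect_identical(read_label_map(p2), lab)
  bad <- file.path(td, "bad.tif")
  tiff::writeTIFF(matrix(7 / 255, 4, 4), bad, bits.per.sample = 8L)
  expect_error(read_label_map(bad), "> 3")
  zero <- file.path(td, "zero.tif")
  write_label_map(matrix(0L, 4, 4), zero)
  expect_true(all(read_label_map(zero) == 0L))
})

test_that("dynamics maps round-trip with NaN exactly where invalid", {
  cfg <- tiny_scene(noise_sigma = 0, noise_prop = 0, bit_depth = NA, seed = 8)
  sim <- render_video(cfg, analytic_truth = FALSE)
  maps <- compute_maps(sim$stack, mask = sim$truth$labels)
  td <- withr::local_tempdir()
  files <- write_maps(maps, td, seed = 8)
  expect_true(all(file.exists(files)))
  maps2 <- read_maps(td)
  expect_identical(maps2$reason, maps$reason)
  codes <- reason_codes()
  valid <- maps$reason %in% c(codes[["ok"]], codes[["censored_half_fall"]])
  # float32 storage: exact to single precision
  expect_equal(maps2$half_rise[valid], maps$half_rise[valid], tolerance = 1e-6)
  expect_equal(maps2$offset[valid], maps$offset[valid], tolerance = 1e-6)
  expect_true(all(is.nan(maps2$half_rise[!valid])))
  expect_true(all(is.nan(maps2$offset[!valid])))
  prov <- jsonlite::read_json(file.path(td, "provenance.json"),
                              simplifyVector = TRUE)
  expect_match(prov$config_hash, "^[0-9a-f]{8}$")
  expect_equal(prov$seed, 8)
})

test_that("manifests round-trip and enforce uniqueness and resolvable paths", {
  td <- withr::local_tempdir()
  for (f in c("v1.tif", "v1.json", "m1.tif")) file.create(file.path(td, f))
  man <- data.frame(animal_id = c("r1", "r2"), site = "retina",
                    group = c("control", "treated"), time_point = "6h",
                    video = "v1.tif", meta = "v1.json", mask = "m1.tif",
                    stringsAsFactors = FALSE)
  mp <- file.path(td, "manifest.csv")
  write_manifest(man, mp)
  m2 <- read_manifest(mp)
  expect_equal(m2$animal_id, c("r1", "r2"))
  dup <- man; dup$animal_id <- "r1"
  write_manifest(dup, mp)
  expect_error(read_manifest(mp), "unique")
  man$video <- "missing.tif"
  write_manifest(man, mp)
  expect_error(read_manifest(mp), "unresolvable")
})
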