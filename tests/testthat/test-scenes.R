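test_that("scene generation is deterministic for identical config and seed", {
  cfg <- scene_config(seed = 99, row_azimuth_deg = 80)
  a <- render_scene(cfg)
  b <- render_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$disparity, b$disparity)
  expect_identical(a$truth$headland, b$truth$headland)
  c <- render_scene(scene_config(seed = 100, row_azimuth_deg = 80))
  expect_false(identical(a$image, c$image))
})

test_that("clutter-free scenes contain exactly three row bands at the true azimuth", {
  sc <- clean_scene(seed = 51, azimuth = 90)
  labs <- EBImage::bwlabel(sc$truth$crop_mask)
  expect_equal(max(labs), 3)
  # the central row images exactly vertically; the outer rows converge
  # slightly toward the vanishing point under perspective
  expect_equal(sc$truth$rows[[2]]$orientation_deg, 90, tolerance = 1e-9)
  for (r in sc$truth$rows) {
    d <- abs(r$orientation_deg - 90) %% 180
    expect_lt(min(d, 180 - d), 10)
  }
  expect_equal(sc$truth$azimuth_deg, 90)
})

test_that("the disparity map is definitionally consistent with the recorded headland depth", {
  sc <- fixture_suite()[[1]]
  s <- sc$camera$stereo
  cp <- sc$truth$headland$center_pixel
  d <- sc$disparity[cp[2] + 1, cp[1] + 1]
  expect_equal(d, s$f * s$B / sc$truth$headland$depth_Zc, tolerance = 1e-9)
  # depth positive wherever disparity is valid
  expect_true(all(sc$disparity >= 0))
  expect_gt(mean(sc$disparity > 0), 0.9)
})

test_that("truth rows project inside the rendered crop mask", {
  sc <- clean_scene(seed = 61, azimuth = 105)
  K <- sc$camera$intrinsics
  hits <- 0; total <- 0
  for (r in sc$truth$rows) {
    for (t in seq(0.02, 0.98, length.out = 25)) {
      w <- r$world_start + t * (r$world_end - r$world_start)
      uv <- project_to_pixel(world_to_camera(w, sc$camera$pose), K)
      ui <- round(uv[1]); vi <- round(uv[2])
      total <- total + 1
      if (ui >= 0 && ui < K$width && vi >= 0 && vi < K$height &&
          sc$truth$crop_mask[vi + 1, ui + 1] == 1) {
        hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("exact-disparity localization recovers the recorded headland position", {
  for (sc in fixture_suite()[c(1, 8, 15)]) {
    loc <- locate_detection(detection(sc$truth$headland$bbox), sc$disparity,
                            sc$camera$stereo, sc$camera$intrinsics,
                            sc$camera$pose)
    err <- sqrt(sum((loc$world_point - sc$truth$headland$world)^2))
    expect_lt(err, 1e-6)
  }
})

test_that("fixture suites are stratified, reproducible, and round-trip through disk", {
  scenes <- fixture_suite()
  expect_length(scenes, 20)
  lv <- attr(scenes, "clutter_levels")
  expect_setequal(unique(lv), c("low", "medium", "high"))
  az <- vapply(scenes, function(s) s$truth$azimuth_deg, numeric(1))
  expect_equal(range(az), c(60, 120))
  # reproducibility: re-rendering a member scene from its config is
  # bit-identical
  again <- render_scene(scenes[[2]]$config)
  expect_identical(scenes[[2]]$image, again$image)
  expect_identical(scenes[[2]]$disparity, again$disparity)
  # disk round trip preserves image bytes and disparity values
  dir <- withr::local_tempdir()
  write_scene(scenes[[1]], file.path(dir, "s1"), clutter = lv[1])
  back <- read_scene(file.path(dir, "s1"))
  expect_lt(max(abs(back$image - scenes[[1]]$image)), 1 / 255 + 1e-9)
  expect_lt(max(abs(back$disparity - scenes[[1]]$disparity)), 1e-12)
  expect_equal(unlist(back$truth$headland$world),
               scenes[[1]]$truth$headland$world,
               tolerance = 1e-12, ignore_attr = TRUE)
})
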