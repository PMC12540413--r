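test_that("rotation_about_x reproduces the closed-form 30-degree matrix and is orthonormal", {
  R30 <- rotation_about_x(30)
  expect_equal(R30,
               matrix(c(1, 0, 0,
                        0, sqrt(3) / 2, -1 / 2,
                        0, 1 / 2, sqrt(3) / 2), nrow = 3, byrow = TRUE),
               tolerance = 1e-15)
  expect_equal(rotation_about_x(0), diag(3))
  expect_equal(drop(rotation_about_x(90) %*% c(0, 1, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  withr::with_seed(42, {
    for (g in stats::runif(20, -180, 180)) {
      R <- rotation_about_x(g)
      expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
  })
})

test_that("camera/world transforms match their printed component forms at 30 degrees", {
  pose <- camera_pose(gamma = 30, T = c(0, 2, 0))
  # forward: Pw = Rx^-1(30) Pc + T, component form
  withr::with_seed(1, {
    pc <- matrix(stats::rnorm(300), ncol = 3)
    pw <- camera_to_world(pc, pose)
    expect_equal(pw[, 1], pc[, 1], tolerance = 1e-12)
    expect_equal(pw[, 2], pc[, 2] * sqrt(3) / 2 + pc[, 3] / 2 + 2,
                 tolerance = 1e-12)
    expect_equal(pw[, 3], -pc[, 2] / 2 + pc[, 3] * sqrt(3) / 2,
                 tolerance = 1e-12)
    # inverse: component form of the world-to-camera expansion
    pc2 <- world_to_camera(pw, pose)
    expect_equal(pc2[, 2], (pw[, 2] - 2) * sqrt(3) / 2 - pw[, 3] / 2,
                 tolerance = 1e-12)
    expect_equal(pc2[, 3], (pw[, 2] - 2) / 2 + pw[, 3] * sqrt(3) / 2,
                 tolerance = 1e-12)
  })
  expect_equal(camera_to_world(c(0, 0, 0), pose), c(0, 2, 0))
  expect_equal(camera_to_world(c(0, 0, 1), pose), c(0, 2.5, sqrt(3) / 2),
               tolerance = 1e-12)
  expect_equal(world_to_camera(c(0, 2, 0), pose), c(0, 0, 0))
  expect_equal(world_to_camera(c(0, 2, 1), pose), c(0, -1 / 2, sqrt(3) / 2),
               tolerance = 1e-12)
})

test_that("world/camera round trip is the identity for arbitrary poses", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      pose <- camera_pose(gamma = stats::runif(1, -90, 90),
                          T = stats::rnorm(3))
      p <- matrix(stats::rnorm(600, sd = 5), ncol = 3)
      expect_lt(max(abs(world_to_camera(camera_to_world(p, pose), pose) - p)),
                1e-9)
      expect_lt(max(abs(camera_to_world(world_to_camera(p, pose), pose) - p)),
                1e-9)
    }
  })
})

test_that("pinhole projection obeys its closed forms and rejects points behind the camera", {
  K <- intrinsics(400, 400, 320, 240, 640, 480)
  expect_equal(project_to_pixel(c(0, 0, 5), K), c(u = 320, v = 240))
  expect_equal(project_to_pixel(c(1, 0, 2), K)[["u"]], 520)
  expect_error(project_to_pixel(c(0, 0, -1), K), "point-behind-camera")
  expect_error(project_to_pixel(c(0, 0, 0), K), "point-behind-camera")
})

test_that("distorted projection matches a term-by-term oracle and inverts cleanly", {
  K <- intrinsics(400, 420, 320, 240, 640, 480)
  dist <- distortion_model(k1 = -0.21, k2 = 0.05, p1 = 1e-3, p2 = -5e-4,
                           k3 = 0.01)
  withr::with_seed(3, {
    for (i in 1:100) {
      p <- c(stats::runif(2, -1, 1), stats::runif(1, 0.5, 5))
      uv <- project_to_pixel(p, K, dist)
      d <- oracle_distort(p[1] / p[3], p[2] / p[3],
                          dist$k1, dist$k2, dist$p1, dist$p2, dist$k3)
      expect_equal(unname(uv), c(K$fx * d[1] + K$cx, K$fy * d[2] + K$cy),
                   tolerance = 1e-9)
    }
    # undistort recovers normalized coordinates (moderate distortion region)
    xn <- stats::runif(50, -0.4, 0.4); yn <- stats::runif(50, -0.4, 0.4)
    fwd <- distort_normalized(xn, yn, dist)
    back <- undistort_normalized(fwd$x, fwd$y, dist)
    expect_lt(max(abs(back$x - xn), abs(back$y - yn)), 1e-9)
  })
  # zero-distortion model is the identity
  z <- distortion_model()
  d0 <- distort_normalized(0.3, -0.2, z)
  expect_identical(c(d0$x, d0$y), c(0.3, -0.2))
})

test_that("clamp_to_image clamps to the border and flags moved points", {
  K <- intrinsics(width = 640, height = 480)
  r <- clamp_to_image(rbind(c(-5, 10), c(100, 100), c(1000, 1000)), K)
  expect_equal(r$u, c(0, 100, 639))
  expect_equal(r$v, c(10, 100, 479))
  expect_equal(r$in_bounds, c(FALSE, TRUE, FALSE))
})

test_that("camera configuration files parse with defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fx: 500", "cx: 310", "gamma_deg: -30"), path)
  cam <- read_camera_config(path)
  expect_equal(cam$intrinsics$fx, 500)
  expect_equal(cam$intrinsics$fy, 400)   # default
  expect_equal(cam$pose$gamma, -30)
  expect_equal(cam$pose$T, c(0, 2, 0))   # default
  expect_equal(cam$stereo$B, 0.075)
})
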