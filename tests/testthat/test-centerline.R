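test_that("collinear points are fitted exactly", {
  l1 <- fit_line(cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(line_angle(l1), 45)
  l2 <- fit_line(cbind(c(0, 10, 20), c(5, 5, 5)))
  expect_equal(line_angle(l2), 0)
  expect_equal(l2$y0, 5)
  # zero perpendicular residual for collinear input
  d <- cbind(c(0, 1, 2) - l1$x0, c(0, 1, 2) - l1$y0)
  res <- d %*% c(-l1$vy, l1$vx)
  expect_lt(max(abs(res)), 1e-12)
  expect_error(fit_line(cbind(c(1, 1), c(2, 2))), "underdetermined-fit")
})

test_that("total least squares matches a brute-force angular grid search on noisy data", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      x <- stats::runif(50, 0, 10)
      y <- 2 * x + 1 + stats::rnorm(50, sd = 0.5)
      pts <- cbind(x, y)
      fitted <- fit_line(pts)
      want <- oracle_tls_angle(pts)
      diff <- abs(fitted$beta_deg %% 180 - want)
      diff <- min(diff, 180 - diff)
      expect_lt(diff, 0.02)  # grid resolution 0.01 degrees
      expect_lt(abs(fitted$beta_deg - atan(2) * 180 / pi), 1)
    }
  })
})

test_that("fit_line is translation invariant and rotation equivariant", {
  withr::with_seed(17, {
    pts <- cbind(stats::runif(30, 0, 10), stats::runif(30, 0, 3))
    base <- fit_line(pts)$beta_deg
    shifted <- fit_line(sweep(pts, 2, c(123.4, -56.7), "+"))$beta_deg
    expect_equal(shifted, base, tolerance = 1e-9)
    for (ang in c(10, 45, 117)) {
      th <- ang * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      rot <- fit_line(pts %*% t(R))$beta_deg
      d <- (rot - base - ang) %% 180
      expect_lt(min(d, 180 - d), 1e-9)
    }
  })
})

test_that("line endpoints follow the image-width closed forms with a vertical guard", {
  l <- line_from_direction(0, 0, 1, 1)
  ep <- line_endpoints(l, 100)
  expect_equal(ep$P_start, c(0, 0))
  expect_equal(ep$P_end, c(100, 100))
  lh <- line_from_direction(30, 7, 1, 0)
  eph <- line_endpoints(lh, 640)
  expect_equal(eph$P_start, c(0, 7))
  expect_equal(eph$P_end, c(640, 7))
  lv <- line_from_direction(50, 10, 0, 1)
  expect_error(line_endpoints(lv, 640), "near-vertical-line")
  # fallback clips to the top/bottom edges
  epv <- line_endpoints_vertical(lv, 480)
  expect_equal(epv$P_start, c(50, 0))
  expect_equal(epv$P_end, c(50, 480))
})

test_that("line_angle reports the two-argument arctangent in (-90, 90]", {
  expect_equal(line_angle(line_from_direction(0, 0, 1, 0)), 0)
  expect_equal(line_angle(line_from_direction(0, 0, sqrt(2) / 2, sqrt(2) / 2)), 45)
  expect_equal(line_angle(line_from_direction(0, 0, 0, 1)), 90)
  expect_equal(line_angle(line_from_direction(0, 0, -1, 1)), -45)
})

test_that("angular deviation handles slopes, wrap-around and perpendicular lines", {
  f45 <- line_from_direction(0, 0, 1, 1)
  s0 <- standard_line(0, 0, 10, 0)
  expect_equal(angle_between(f45, s0)$abs_theta, 45)
  # identical lines
  expect_equal(angle_between(f45, standard_line(0, 0, 5, 5))$theta, 0)
  # wrap-around: 80 vs -80 degrees -> 20, not 160
  f80 <- line_from_direction(0, 0, cos(80 * pi / 180), sin(80 * pi / 180))
  sm80 <- standard_line(0, 0, cos(-80 * pi / 180), sin(-80 * pi / 180))
  expect_equal(angle_between(f80, sm80)$abs_theta, 20, tolerance = 1e-9)
  # matches the slope formula when both slopes are defined
  m1 <- 0.3; m2 <- 1.7
  fa <- line_from_direction(0, 0, 1, m2)
  sb <- standard_line(0, 0, 1, m1)
  expect_equal(angle_between(fa, sb)$abs_theta,
               atan(abs((m2 - m1) / (1 + m2 * m1))) * 180 / pi,
               tolerance = 1e-9)
  # perpendicular: m1 m2 = -1 must not blow up
  fp <- line_from_direction(0, 0, 1, 1)
  sp <- standard_line(0, 0, 1, -1)
  expect_equal(angle_between(fp, sp)$abs_theta, 90)
  # symmetric in magnitude
  expect_equal(angle_between(fa, sb)$abs_theta,
               angle_between(line_from_direction(0, 0, 1, m1),
                             standard_line(0, 0, 1, m2))$abs_theta,
               tolerance = 1e-9)
  # sign: fitted leaning left of a vertical standard (upper end at smaller u)
  # in image coordinates is negative
  fl <- line_from_direction(100, 100, cos(80 * pi / 180), sin(80 * pi / 180))
  sv <- standard_line(100, 0, 100, 200)
  expect_lt(angle_between(fl, sv)$theta, 0)
})

test_that("deviation summaries reproduce the bundled angular-deviation statistics", {
  th <- angular_samples()$theta_deg
  s <- summarize_deviations(th)
  expect_equal(s$n, 11L)
  expect_equal(round(s$mean, 3), -0.473)
  expect_equal(round(s$mae, 3), 3.309)
  expect_equal(s$max_abs, 7.000)
  expect_gte(s$mae, abs(s$mean))
  expect_gte(s$max_abs, s$mae)
  expect_equal(unclass(summarize_deviations(c(0, 0)))[1:3],
               list(mean = 0, mae = 0, max_abs = 0))
  s2 <- summarize_deviations(c(3, -3))
  expect_equal(c(s2$mean, s2$mae, s2$max_abs), c(0, 3, 3))
  expect_error(summarize_deviations(numeric(0)), "no-data")
})
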