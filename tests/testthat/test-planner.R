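test_that("arc radius takes the shorter target coordinate and enforces R_min", {
  expect_equal(arc_radius(planner_input(2, 5, 90)), 2)
  expect_equal(arc_radius(planner_input(-4, 3, 90)), 3)
  expect_error(arc_radius(planner_input(1, 5, 90, R_min = 1.5)),
               "infeasible-turn")
})

test_that("arc center follows the printed case split", {
  expect_equal(arc_center(planner_input(2, 5, 90), 2), c(2, 0, 3))
  expect_equal(arc_center(planner_input(-6, 3, 90), 3), c(-3, 0, 0))
  expect_equal(arc_center(planner_input(4, 4, 90), 4), c(4, 0, 0))
  expect_equal(arc_center(planner_input(-2, 5, 90), 2), c(-2, 0, 3))
})

test_that("the swept angle branches partition the half turn", {
  expect_equal(arc_angle(90), 90)
  expect_equal(arc_angle(-30), 150)
  expect_error(arc_angle(0), "degenerate-azimuth")
  expect_error(planner_input(2, 5, 0), "degenerate-azimuth")
  # the positive and negative branches partition the half turn
  for (b in seq(1, 179, by = 1)) {
    expect_equal(arc_angle(b) + arc_angle(-b), 180)
  }
})

test_that("sampled arcs start on the forward axis and lie exactly on the circle", {
  # |Xw| < |Zw| case: quarter arc ends exactly on the target
  spec <- arc_spec(planner_input(2, 5, 90))
  pts <- sample_arc(spec, 101)
  expect_equal(pts[1, ], c(0, 0, 3), tolerance = 1e-12)
  expect_equal(pts[101, ], c(2, 0, 5), tolerance = 1e-12)
  radii <- sqrt(rowSums(sweep(pts, 2, spec$O)^2))
  expect_lt(max(abs(radii - spec$R)), 1e-12)
  # |Zw| <= |Xw| case: the arc starts at the origin
  spec2 <- arc_spec(planner_input(6, 3, 90))
  expect_equal(sample_arc(spec2, 10)[1, ], c(0, 0, 0), tolerance = 1e-12)
})

test_that("mirroring the lateral target mirrors the whole path", {
  p1 <- plan_turn(planner_input(2, 5, 90), n = 50)
  p2 <- plan_turn(planner_input(-2, 5, 90), n = 50)
  expect_equal(p1$waypoints[, 1], -p2$waypoints[, 1], tolerance = 1e-12)
  expect_equal(p1$waypoints[, 3], p2$waypoints[, 3], tolerance = 1e-12)
})

test_that("natural spline coefficients match stats::splinefun and are C2 continuous", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      x <- sort(stats::runif(n, 0, 10))
      while (min(diff(x)) < 1e-3) x <- sort(stats::runif(n, 0, 10))
      y <- stats::rnorm(n)
      sp <- natural_cubic_spline(x, y)
      ref <- stats::splinefun(x, y, method = "natural")
      xx <- seq(min(x), max(x), length.out = 200)
      expect_lt(max(abs(eval_spline(sp, xx) - ref(xx))), 1e-9)
      # knots reproduce the data
      expect_lt(max(abs(eval_spline(sp, x) - y)), 1e-12)
      # C0/C1/C2 continuity at interior knots
      for (i in seq_len(nrow(sp) - 1)) {
        xk <- sp$x_hi[i]
        hu <- xk - sp$x_lo[i]
        for (d in 0:2) {
          left <- switch(as.character(d),
                         "0" = sp$a[i] + sp$b[i] * hu + sp$c[i] * hu^2 + sp$d[i] * hu^3,
                         "1" = sp$b[i] + 2 * sp$c[i] * hu + 3 * sp$d[i] * hu^2,
                         "2" = 2 * sp$c[i] + 6 * sp$d[i] * hu)
          right <- switch(as.character(d),
                          "0" = sp$a[i + 1], "1" = sp$b[i + 1],
                          "2" = 2 * sp$c[i + 1])
          expect_lt(abs(left - right), 1e-9)
        }
      }
      # natural boundary: zero curvature at both ends
      expect_lt(abs(eval_spline(sp, x[1], deriv = 2)), 1e-9)
      expect_lt(abs(eval_spline(sp, x[n], deriv = 2)), 1e-9)
    }
  })
})

test_that("plan_turn composes lead-in, arc and an interpolating smoothing spline", {
  path <- plan_turn(planner_input(2, 5, 90), n = 100)
  wp <- path$waypoints
  # starts at the origin, ends on the target (quarter-arc case)
  expect_equal(wp[1, ], c(0, 0, 0), tolerance = 1e-12)
  expect_equal(wp[nrow(wp), ], c(2, 0, 5), tolerance = 1e-12)
  expect_equal(path$terminal_offset, 0, tolerance = 1e-12)
  # lead-in runs straight up the forward axis to the arc start (0, 0, 3)
  lead <- wp[wp[, 3] <= 3 & wp[, 1] == 0, ]
  expect_gt(nrow(lead), 2)
  # path length bounds below by the straight-line distance
  seg <- sqrt(rowSums(diff(wp)^2))
  expect_gte(sum(seg), sqrt(sum(wp[nrow(wp), ]^2)))
  # spline interpolates the waypoints at the chord-length knots
  expect_lt(max(abs(eval_spline(path$spline_x, path$s) - wp[, 1])), 1e-9)
  expect_lt(max(abs(eval_spline(path$spline_z, path$s) - wp[, 3])), 1e-9)
  # errors propagate
  expect_error(plan_turn(planner_input(1, 5, 90)), "infeasible-turn")
})
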