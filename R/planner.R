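#' Planner input
#'
#' Target position in the ground plane of the world frame plus the crop-row
#' azimuth and the vehicle's minimum turning radius.
#'
#' @param Xw,Zw Target world coordinates, meters (not both zero). X is
#'   lateral (positive left), Z forward.
#' @param beta_deg Crop-row azimuth in degrees, in `(-180, 180]`, nonzero.
#' @param R_min Minimum turning radius, meters.
#' @return An object of class `planner_input`.
#' @export
planner_input <- function(Xw, Zw, beta_deg, R_min = 1.5) {
  stopifnot(is.finite(Xw), is.finite(Zw), is.finite(beta_deg), R_min > 0,
            beta_deg > -180, beta_deg <= 180)
  if (Xw == 0 && Zw == 0) {
    stop("invalid-input: target coincides with the vehicle origin",
         call. = FALSE)
  }
  if (beta_deg == 0) {
    stop("degenerate-azimuth: beta_deg must be nonzero", call. = FALSE)
  }
  structure(list(Xw = Xw, Zw = Zw, beta_deg = beta_deg, R_min = R_min),
            class = "planner_input")
}

#' Arc turning radius
#'
#' `R = min(|Xw|, |Zw|)`, constrained to exceed the minimum turning radius.
#'
#' @param inp A [planner_input()].
#' @return Radius in meters.
#' @export
arc_radius <- function(inp) {
  R <- min(abs(inp$Xw), abs(inp$Zw))
  if (R <= inp$R_min) {
    stop(sprintf("infeasible-turn: R = %.3f m does not exceed R_min = %.3f m",
                 R, inp$R_min), call. = FALSE)
  }
  R
}

#' Arc center
#'
#' Case split on which coordinate sets the radius: when `R = |Xw| < |Zw|` the
#' center is `(sign(Xw) R, 0, Zw - R)`; when `R = |Zw| <= |Xw|` it is
#' `(sign(Xw) R, 0, 0)`.
#'
#' @param inp A [planner_input()].
#' @param R Radius from [arc_radius()].
#' @return World 3-vector `c(X, 0, Z)`.
#' @export
arc_center <- function(inp, R) {
  sgn <- sign(inp$Xw)
  if (abs(inp$Xw) < abs(inp$Zw)) {
    c(sgn * R, 0, inp$Zw - R)
  } else {
    c(sgn * R, 0, 0)
  }
}

#' Swept arc angle from the crop-row azimuth
#'
#' `alpha = beta_deg` for positive azimuths, `alpha = 180 + beta_deg` for
#' negative ones; the two branches partition the half turn.
#'
#' @param beta_deg Azimuth in degrees, nonzero.
#' @return Swept angle in degrees, in `(0, 180]`.
#' @export
arc_angle <- function(beta_deg) {
  stopifnot(is.finite(beta_deg))
  if (beta_deg == 0) {
    stop("degenerate-azimuth: beta_deg must be nonzero", call. = FALSE)
  }
  if (beta_deg > 0) beta_deg else 180 + beta_deg
}

#' Full arc specification
#'
#' @param inp A [planner_input()].
#' @return An object of class `arc_spec` with `R` (m), `O` (world 3-vector),
#'   `alpha` (degrees), `turn_direction` ("left" for Xw > 0) and the sign of
#'   Xw used to orient the parameterization.
#' @export
arc_spec <- function(inp) {
  R <- arc_radius(inp)
  O <- arc_center(inp, R)
  alpha <- arc_angle(inp$beta_deg)
  structure(list(R = R, O = O, alpha = alpha,
                 turn_direction = if (inp$Xw > 0) "left" else "right",
                 sgn = sign(inp$Xw)),
            class = "arc_spec")
}

#' @export
print.arc_spec <- function(x, ...) {
  cat(sprintf("arc_spec: R=%.3f m, O=(%.3f, %.3f, %.3f), alpha=%.3f deg, %s turn\n",
              x$R, x$O[1], x$O[2], x$O[3], x$alpha, x$turn_direction))
  invisible(x)
}

#' Sample waypoints along the arc
#'
#' `P(t) = O + R (-sgn cos t, 0, sin t)` for `t` uniform on `[0, alpha]`,
#' where `sgn = sign(Xw)`. The start point `P(0)` lies on the vehicle's
#' forward axis (`X = 0`).
#'
#' @param spec An [arc_spec()].
#' @param n Number of samples (>= 2).
#' @return n x 3 matrix of world waypoints (Y = 0).
#' @export
sample_arc <- function(spec, n = 100) {
  stopifnot(n >= 2)
  t <- seq(0, spec$alpha * pi / 180, length.out = n)
  cbind(spec$O[1] - spec$sgn * spec$R * cos(t),
        0,
        spec$O[3] + spec$R * sin(t))
}

#' Natural cubic spline coefficients
#'
#' Interpolating natural cubic spline (zero second derivative at both ends)
#' through `(x, y)`, solved with the standard tridiagonal system (Thomas
#' algorithm). On `[x_i, x_{i+1}]` the segment is
#' `S_i(u) = a_i + b_i (u - x_i) + c_i (u - x_i)^2 + d_i (u - x_i)^3`.
#'
#' @param x Strictly increasing knot positions.
#' @param y Values at the knots.
#' @return An object of class `cubic_spline`: data.frame with columns `a`,
#'   `b`, `c`, `d`, `x_lo`, `x_hi`.
#' @export
natural_cubic_spline <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, all(diff(x) > 0))
  n <- length(x)
  h <- diff(x)
  if (n == 2) {
    seg <- data.frame(a = y[1], b = (y[2] - y[1]) / h[1], c = 0, d = 0,
                      x_lo = x[1], x_hi = x[2])
    return(structure(seg, class = c("cubic_spline", "data.frame")))
  }
  # tridiagonal system in the interior second derivatives M_2..M_{n-1};
  # row i (unknown M_{i+1}): h_i M_i + 2(h_i + h_{i+1}) M_{i+1} + h_{i+1} M_{i+2}
  m <- n - 2
  i <- seq_len(m)
  diag0 <- 2 * (h[i] + h[i + 1])
  rhs <- 6 * ((y[i + 2] - y[i + 1]) / h[i + 1] - (y[i + 1] - y[i]) / h[i])
  off <- h[i + 1][-m]  # symmetric sub/super diagonal between unknowns
  # Thomas algorithm
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- if (m > 1) off[1] / diag0[1] else 0
  dp[1] <- rhs[1] / diag0[1]
  if (m > 1) {
    for (k in 2:m) {
      denom <- diag0[k] - off[k - 1] * cp[k - 1]
      if (k < m) cp[k] <- off[k] / denom
      dp[k] <- (rhs[k] - off[k - 1] * dp[k - 1]) / denom
    }
  }
  M <- numeric(n)  # second derivatives, natural BCs: M[1] = M[n] = 0
  M[m + 1] <- dp[m]
  if (m > 1) for (k in (m - 1):1) M[k + 1] <- dp[k] - cp[k] * M[k + 2]
  i <- seq_len(n - 1)
  a <- y[i]
  b <- diff(y) / h - h * (2 * M[i] + M[i + 1]) / 6
  cc <- M[i] / 2
  d <- (M[i + 1] - M[i]) / (6 * h)
  seg <- data.frame(a = a, b = b, c = cc, d = d, x_lo = x[i], x_hi = x[i + 1])
  structure(seg, class = c("cubic_spline", "data.frame"))
}

#' Evaluate a cubic spline
#'
#' @param spline A [natural_cubic_spline()] result.
#' @param xout Evaluation points (clamped extrapolation uses the end
#'   segments).
#' @param deriv Derivative order 0, 1 or 2.
#' @return Numeric vector of values.
#' @export
eval_spline <- function(spline, xout, deriv = 0) {
  idx <- findInterval(xout, spline$x_lo, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > nrow(spline)] <- nrow(spline)
  u <- xout - spline$x_lo[idx]
  a <- spline$a[idx]; b <- spline$b[idx]; cc <- spline$c[idx]; d <- spline$d[idx]
  switch(as.character(deriv),
         "0" = a + b * u + cc * u^2 + d * u^3,
         "1" = b + 2 * cc * u + 3 * d * u^2,
         "2" = 2 * cc + 6 * d * u,
         stop("deriv must be 0, 1 or 2"))
}

#' Plan a headland turn
#'
#' Builds the arc from the planner input, prepends a straight lead-in from
#' the vehicle origin to the arc's start point (empty when they coincide),
#' and re-smooths the combined waypoints with natural cubic splines in X and
#' Z parameterized by cumulative chord length. The terminal-to-target
#' distance is reported as a diagnostic: for targets with `|Zw| <= |Xw|` the
#' printed center rule cannot make the arc end exactly on the target.
#'
#' @param inp A [planner_input()].
#' @param n Number of arc samples (default 100); the lead-in is sampled at
#'   the same spacing.
#' @return An object of class `planned_path`: `waypoints` (m x 3 matrix),
#'   `spline_x`, `spline_z` ([natural_cubic_spline()] objects on chord
#'   length), `s` (knots), `smoothed` (denser spline evaluation), `spec`,
#'   `terminal_offset` (m).
#' @export
plan_turn <- function(inp, n = 100) {
  spec <- arc_spec(inp)
  arc <- sample_arc(spec, n)
  start <- arc[1, ]
  lead_len <- sqrt(sum(start^2))
  if (lead_len > 1e-12) {
    spacing <- spec$R * spec$alpha * pi / 180 / (n - 1)
    m <- max(2, ceiling(lead_len / spacing) + 1)
    lead <- cbind(seq(0, start[1], length.out = m),
                  0,
                  seq(0, start[3], length.out = m))
    waypoints <- rbind(lead[-m, , drop = FALSE], arc)
  } else {
    waypoints <- arc
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(waypoints)^2))))
  sx <- natural_cubic_spline(s, waypoints[, 1])
  sz <- natural_cubic_spline(s, waypoints[, 3])
  sd <- seq(0, max(s), length.out = 2 * nrow(waypoints))
  smoothed <- cbind(eval_spline(sx, sd), 0, eval_spline(sz, sd))
  target <- c(inp$Xw, 0, inp$Zw)
  structure(list(waypoints = waypoints, spline_x = sx, spline_z = sz,
                 s = s, smoothed = smoothed, spec = spec,
                 terminal_offset = sqrt(sum((waypoints[nrow(waypoints), ] - target)^2))),
            class = "planned_path")
}

#' @export
print.planned_path <- function(x, ...) {
  print(x$spec)
  cat(sprintf("planned_path: %d waypoints, chord length %.3f m, terminal offset %.3f m\n",
              nrow(x$waypoints), max(x$s), x$terminal_offset))
  invisible(x)
}
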