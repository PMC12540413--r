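# Wrap an undirected line orientation (degrees) into (-90, 90].
wrap_orientation <- function(deg) {
  out <- (deg %% 180)
  out[out > 90] <- out[out > 90] - 180
  # map -90 to +90 (undirected lines)
  out[out == -90] <- 90
  out
}

#' Fit a straight centerline through feature points (total least squares)
#'
#' Orthogonal least squares: the line passes through the centroid of the
#' points and runs along the principal axis of their scatter, minimizing the
#' sum of squared perpendicular distances. The direction is canonicalized to
#' `vy >= 0` (ties broken toward `vx > 0`).
#'
#' @param points n x 2 matrix or data.frame of (x, y); at least two distinct
#'   points are required.
#' @return An object of class `fitted_line` with `x0`, `y0`, `vx`, `vy`,
#'   `beta` (radians) and `beta_deg` (orientation in `(-90, 90]`).
#' @export
fit_line <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  stopifnot(is.matrix(points), ncol(points) == 2)
  pts <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(unique(pts)) < 2) {
    stop("underdetermined-fit: need at least 2 distinct points", call. = FALSE)
  }
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  S <- crossprod(d) / nrow(d)
  ev <- eigen(S, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  beta <- atan2(v[2], v[1])
  structure(list(x0 = unname(ctr[1]), y0 = unname(ctr[2]),
                 vx = v[1], vy = v[2],
                 beta = beta,
                 beta_deg = wrap_orientation(beta * 180 / pi),
                 n = nrow(pts)),
            class = "fitted_line")
}

#' Construct a fitted_line from a point and direction
#'
#' @param x0,y0 A point on the line.
#' @param vx,vy Direction (normalized internally).
#' @return A `fitted_line`.
#' @export
line_from_direction <- function(x0, y0, vx, vy) {
  n <- sqrt(vx^2 + vy^2)
  stopifnot(n > 0)
  v <- c(vx, vy) / n
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  beta <- atan2(v[2], v[1])
  structure(list(x0 = x0, y0 = y0, vx = v[1], vy = v[2], beta = beta,
                 beta_deg = wrap_orientation(beta * 180 / pi), n = NA),
            class = "fitted_line")
}

#' @export
print.fitted_line <- function(x, ...) {
  cat(sprintf("fitted_line: through (%.2f, %.2f), direction (%.4f, %.4f), %.3f deg\n",
              x$x0, x$y0, x$vx, x$vy, x$beta_deg))
  invisible(x)
}

#' Line endpoints at the left and right image edges
#'
#' `P_start = (0, y|x=0)`, `P_end = (W, y|x=W)`. Near-vertical lines (|vx|
#' below `eps`) cannot be expressed this way and raise an error; callers
#' should fall back to top/bottom-edge intersections.
#'
#' @param line A `fitted_line`.
#' @param W Image width, pixels.
#' @param eps Guard on `|vx|` (default 1e-6).
#' @return List with `P_start` and `P_end` (each `c(x, y)`).
#' @export
line_endpoints <- function(line, W, eps = 1e-6) {
  if (abs(line$vx) < eps) {
    stop("near-vertical-line: endpoints at x = 0 and x = W are undefined",
         call. = FALSE)
  }
  m <- line$vy / line$vx
  list(P_start = c(0, line$y0 - line$x0 * m),
       P_end = c(W, line$y0 + (W - line$x0) * m))
}

#' Endpoints of a line clipped to the top and bottom image edges
#'
#' Fallback for near-vertical lines: intersections with `y = 0` and `y = H`.
#'
#' @param line A `fitted_line`.
#' @param H Image height, pixels.
#' @param eps Guard on `|vy|`.
#' @return List with `P_start` (top) and `P_end` (bottom).
#' @export
line_endpoints_vertical <- function(line, H, eps = 1e-6) {
  if (abs(line$vy) < eps) {
    stop("near-horizontal-line: endpoints at y = 0 and y = H are undefined",
         call. = FALSE)
  }
  m <- line$vx / line$vy
  list(P_start = c(line$x0 - line$y0 * m, 0),
       P_end = c(line$x0 + (H - line$y0) * m, H))
}

#' Orientation angle of a fitted line
#'
#' The two-argument arctangent of the direction vector, in degrees, reported
#' as an undirected orientation relative to the horizontal image axis in
#' `(-90, 90]`.
#'
#' @param line A `fitted_line`.
#' @return Degrees.
#' @export
line_angle <- function(line) {
  line$beta_deg
}

#' A reference (standard) line from two endpoints
#'
#' Used as ground truth when scoring fitted centerlines: in evaluation the
#' standard line joins the midpoints of the top and bottom edges of a crop
#' row.
#'
#' @param x1,y1,x2,y2 Endpoint pixel coordinates (distinct points).
#' @return An object of class `standard_line` with the endpoints, `slope`
#'   (NA when vertical) and `beta_deg` orientation in `(-90, 90]`.
#' @export
standard_line <- function(x1, y1, x2, y2) {
  x1 <- unname(x1); y1 <- unname(y1); x2 <- unname(x2); y2 <- unname(y2)
  stopifnot(x1 != x2 || y1 != y2)
  slope <- if (x2 == x1) NA_real_ else (y2 - y1) / (x2 - x1)
  beta <- atan2(y2 - y1, x2 - x1) * 180 / pi
  structure(list(p1 = c(x1, y1), p2 = c(x2, y2), slope = slope,
                 beta_deg = wrap_orientation(beta)),
            class = "standard_line")
}

#' Signed angular deviation between a fitted and a standard line
#'
#' The magnitude matches the slope formula
#' `theta = atan(|m2 - m1| / |1 + m2 m1|)`, but is computed from the
#' orientation difference (fitted minus standard, wrapped to `(-90, 90]`) so
#' that perpendicular configurations (`m1 m2 = -1`) and vertical lines need
#' no special casing. In image coordinates (v down) a negative value means
#' the fitted line leans to the left of the standard line (its upper end sits
#' at a smaller u).
#'
#' @param fitted A `fitted_line` (or anything with `beta_deg`).
#' @param standard A `standard_line` (or anything with `beta_deg`).
#' @return An object of class `angle_deviation` with `theta` and `abs_theta`
#'   (degrees).
#' @export
angle_between <- function(fitted, standard) {
  theta <- wrap_orientation(fitted$beta_deg - standard$beta_deg)
  structure(list(theta = theta, abs_theta = abs(theta)),
            class = "angle_deviation")
}

#' Summary statistics of angular deviations
#'
#' @param devs Numeric vector of signed deviations (degrees), or a list of
#'   `angle_deviation` objects.
#' @return An object of class `deviation_summary` with `mean`, `mae`,
#'   `max_abs` and `n`.
#' @examples
#' summarize_deviations(c(-3.9, 0.9, 1.0, -5.0))
#' @export
summarize_deviations <- function(devs) {
  if (is.list(devs) && !is.data.frame(devs)) {
    devs <- vapply(devs, function(d) d$theta, numeric(1))
  }
  devs <- as.numeric(devs)
  if (length(devs) == 0) {
    stop("no-data: cannot summarize an empty deviation set", call. = FALSE)
  }
  structure(list(mean = mean(devs), mae = mean(abs(devs)),
                 max_abs = max(abs(devs)), n = length(devs)),
            class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf("deviation_summary: n=%d mean=%.3f deg  MAE=%.3f deg  max=%.3f deg\n",
              x$n, x$mean, x$mae, x$max_abs))
  invisible(x)
}
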