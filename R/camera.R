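#' Camera intrinsics
#'
#' Pinhole intrinsic parameters in pixel units. The principal point must lie
#' inside the image; pixel centers sit at integer coordinates with the origin
#' at the top-left corner, `u` rightward and `v` downward.
#'
#' @param fx,fy Focal lengths in pixel units (horizontal, vertical).
#' @param cx,cy Principal-point pixel coordinates.
#' @param width,height Image dimensions in pixels.
#' @return An object of class `intrinsics`.
#' @examples
#' K <- intrinsics(400, 400, 320, 240, 640, 480)
#' @export
intrinsics <- function(fx = 400, fy = 400, cx = 320, cy = 240,
                       width = 640, height = 480) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1,
            cx >= 0, cx < width, cy >= 0, cy < height)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "intrinsics")
}

#' @export
print.intrinsics <- function(x, ...) {
  cat(sprintf("intrinsics: fx=%.6g fy=%.6g cx=%.6g cy=%.6g (%dx%d px)\n",
              x$fx, x$fy, x$cx, x$cy, x$width, x$height))
  invisible(x)
}

#' Intrinsic matrix K
#'
#' @param K An [intrinsics()] object.
#' @return The 3x3 intrinsic matrix.
#' @export
intrinsic_matrix <- function(K) {
  matrix(c(K$fx, 0, K$cx,
           0, K$fy, K$cy,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Lens distortion model
#'
#' Five-coefficient radial-tangential model (k1, k2, k3 radial; p1, p2
#' tangential) applied to normalized image coordinates before the intrinsic
#' mapping. The all-zero model is the identity.
#'
#' @param k1,k2,k3 Radial coefficients.
#' @param p1,p2 Tangential coefficients.
#' @return An object of class `distortion_model`.
#' @export
distortion_model <- function(k1 = 0, k2 = 0, p1 = 0, p2 = 0, k3 = 0) {
  co <- c(k1 = k1, k2 = k2, p1 = p1, p2 = p2, k3 = k3)
  stopifnot(all(is.finite(co)))
  structure(as.list(co), class = "distortion_model")
}

#' Camera pose: pitch about the world X axis plus translation
#'
#' The world frame has Z forward, Y up (height above ground) and X lateral,
#' positive to the left of the Z axis. The camera frame is related to it by a
#' rotation of `gamma` degrees about the world X axis and a translation `T`
#' (the camera origin expressed in world coordinates).
#'
#' @param gamma Pitch angle in degrees.
#' @param T World-frame translation of the camera origin, meters (3-vector).
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(gamma = 30, T = c(0, 2, 0)) {
  stopifnot(is.finite(gamma), length(T) == 3, all(is.finite(T)))
  structure(list(gamma = gamma, T = as.numeric(T)), class = "camera_pose")
}

#' Rotation matrix about the X axis
#'
#' @param gamma Angle in degrees.
#' @return 3x3 orthonormal rotation matrix with determinant 1.
#' @examples
#' rotation_about_x(30)  # entries cos30 = sqrt(3)/2, sin30 = 1/2
#' @export
rotation_about_x <- function(gamma) {
  stopifnot(is.finite(gamma))
  g <- gamma * pi / 180
  matrix(c(1, 0, 0,
           0, cos(g), -sin(g),
           0, sin(g), cos(g)), nrow = 3, byrow = TRUE)
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3)
    p <- matrix(p, nrow = 1)
  }
  stopifnot(ncol(p) == 3)
  p
}

#' Camera-to-world rigid transform
#'
#' Applies `P_w = R_x(gamma)^-1 P_c + T`. Accepts a 3-vector or an n x 3
#' matrix of points (one per row); returns the same shape.
#'
#' @param p Camera-frame point(s), meters.
#' @param pose A [camera_pose()].
#' @return World-frame point(s).
#' @export
camera_to_world <- function(p, pose) {
  vec <- is.null(dim(p))
  pm <- as_point_matrix(p)
  Rinv <- t(rotation_about_x(pose$gamma))
  out <- pm %*% t(Rinv)
  out <- sweep(out, 2, pose$T, "+")
  if (vec) drop(out) else out
}

#' World-to-camera rigid transform
#'
#' Exact inverse of [camera_to_world()]: `P_c = R_x(gamma) (P_w - T)`.
#'
#' @inheritParams camera_to_world
#' @param p World-frame point(s), meters.
#' @return Camera-frame point(s).
#' @export
world_to_camera <- function(p, pose) {
  vec <- is.null(dim(p))
  pm <- as_point_matrix(p)
  R <- rotation_about_x(pose$gamma)
  out <- sweep(pm, 2, pose$T, "-") %*% t(R)
  if (vec) drop(out) else out
}

#' Apply the radial-tangential distortion model to normalized coordinates
#'
#' @param xn,yn Normalized image coordinates (Xc/Zc, Yc/Zc), vectors.
#' @param dist A [distortion_model()] (or NULL for identity).
#' @return A list with distorted `x` and `y`.
#' @export
distort_normalized <- function(xn, yn, dist = NULL) {
  if (is.null(dist)) return(list(x = xn, y = yn))
  r2 <- xn^2 + yn^2
  radial <- 1 + dist$k1 * r2 + dist$k2 * r2^2 + dist$k3 * r2^3
  xd <- xn * radial + 2 * dist$p1 * xn * yn + dist$p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + dist$p1 * (r2 + 2 * yn^2) + 2 * dist$p2 * xn * yn
  list(x = xd, y = yd)
}

#' Invert the distortion model (iteratively)
#'
#' Fixed-point inversion of [distort_normalized()]; with an all-zero model the
#' input is returned unchanged.
#'
#' @inheritParams distort_normalized
#' @param xd,yd Distorted normalized coordinates.
#' @param max_iter,tol Iteration controls.
#' @return A list with undistorted `x` and `y`.
#' @export
undistort_normalized <- function(xd, yd, dist = NULL, max_iter = 50, tol = 1e-12) {
  if (is.null(dist)) return(list(x = xd, y = yd))
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    d <- distort_normalized(x, y, dist)
    ex <- d$x - xd; ey <- d$y - yd
    x <- x - ex; y <- y - ey
    if (max(abs(ex), abs(ey)) < tol) break
  }
  list(x = x, y = y)
}

#' Project camera-frame points to pixel coordinates
#'
#' `u = fx Xc/Zc + cx`, `v = fy Yc/Zc + cy`, with the distortion model applied
#' to the normalized coordinates first. All points must be in front of the
#' camera (`Zc > 0`).
#'
#' @param p Camera-frame point(s): 3-vector or n x 3 matrix.
#' @param K An [intrinsics()].
#' @param dist Optional [distortion_model()].
#' @return An n x 2 matrix of (u, v) pixel coordinates (a length-2 vector for
#'   a single point).
#' @export
project_to_pixel <- function(p, K, dist = NULL) {
  vec <- is.null(dim(p))
  pm <- as_point_matrix(p)
  if (any(pm[, 3] <= 0)) {
    stop("point-behind-camera: projection requires Zc > 0", call. = FALSE)
  }
  xn <- pm[, 1] / pm[, 3]
  yn <- pm[, 2] / pm[, 3]
  d <- distort_normalized(xn, yn, dist)
  uv <- cbind(u = K$fx * d$x + K$cx, v = K$fy * d$y + K$cy)
  if (vec) drop(uv) else uv
}

#' Clamp pixel coordinates to the image boundary
#'
#' Coordinates are clamped to `[0, width-1] x [0, height-1]`. The `in_bounds`
#' column records whether a point was already inside (TRUE) or had to be
#' moved to the border (FALSE).
#'
#' @param p Pixel point(s): length-2 vector or n x 2 matrix of (u, v).
#' @param K An [intrinsics()] supplying the image size.
#' @return A data.frame with columns `u`, `v`, `in_bounds`.
#' @export
clamp_to_image <- function(p, K) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  stopifnot(ncol(p) == 2, all(is.finite(p)))
  u <- pmin(pmax(p[, 1], 0), K$width - 1)
  v <- pmin(pmax(p[, 2], 0), K$height - 1)
  data.frame(u = u, v = v, in_bounds = (u == p[, 1]) & (v == p[, 2]))
}

#' Read a camera configuration file
#'
#' YAML or JSON with keys `fx, fy, cx, cy, width, height`, optional
#' `distortion` (list `[k1, k2, p1, p2, k3]`), `gamma_deg`, `T` (3-vector),
#' and optional stereo parameters `stereo_f`, `stereo_b`. Missing keys take
#' the defaults `gamma_deg = 30`, `T = c(0, 2, 0)`, zero distortion.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A list with elements `intrinsics`, `distortion`, `pose`, `stereo`.
#' @export
read_camera_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  camera_from_list(cfg)
}

camera_from_list <- function(cfg) {
  K <- intrinsics(fx = cfg$fx %||% 400, fy = cfg$fy %||% 400,
                  cx = cfg$cx %||% 320, cy = cfg$cy %||% 240,
                  width = cfg$width %||% 640, height = cfg$height %||% 480)
  dc <- cfg$distortion %||% c(0, 0, 0, 0, 0)
  dc <- c(as.numeric(dc), rep(0, 5))[1:5]  # order k1, k2, p1, p2, k3
  dist <- distortion_model(k1 = dc[1], k2 = dc[2], p1 = dc[3],
                           p2 = dc[4], k3 = dc[5])
  pose <- camera_pose(gamma = cfg$gamma_deg %||% 30,
                      T = as.numeric(cfg$T %||% c(0, 2, 0)))
  stereo <- stereo_params(f = cfg$stereo_f %||% K$fx,
                          B = cfg$stereo_b %||% 0.075)
  list(intrinsics = K, distortion = dist, pose = pose, stereo = stereo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
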