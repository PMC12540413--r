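#' Stereo parameters
#'
#' @param f Focal length in pixels (of the rectified stereo pair).
#' @param B Baseline between the two cameras, meters.
#' @return An object of class `stereo_params`.
#' @export
stereo_params <- function(f = 400, B = 0.075) {
  stopifnot(f > 0, B > 0)
  structure(list(f = f, B = B), class = "stereo_params")
}

#' Depth from disparity
#'
#' Triangulation: `Zc = f * B / d`. Disparities must be strictly positive;
#' zero or negative values are invalid measurements.
#'
#' @param d Disparity in pixels (vectorized).
#' @param s A [stereo_params()].
#' @return Depth(s) in meters.
#' @examples
#' depth_from_disparity(30, stereo_params(400, 0.075))  # 1 m
#' @export
depth_from_disparity <- function(d, s) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("invalid-disparity: disparity must be finite and > 0", call. = FALSE)
  }
  s$f * s$B / d
}

#' Back-project a pixel to camera coordinates at a known depth
#'
#' `Xc = (u - cx) Zc / fx`, `Yc = (v - cy) Zc / fy`.
#'
#' @param u,v Pixel coordinates (vectorized).
#' @param Zc Depth(s) in meters, all > 0.
#' @param K An [intrinsics()].
#' @return An n x 3 matrix of camera-frame points (3-vector for one point).
#' @export
pixel_to_camera_3d <- function(u, v, Zc, K) {
  if (any(!is.finite(Zc)) || any(Zc <= 0)) {
    stop("invalid-depth: Zc must be finite and > 0", call. = FALSE)
  }
  out <- cbind(Xc = (u - K$cx) * Zc / K$fx,
               Yc = (v - K$cy) * Zc / K$fy,
               Zc = Zc + numeric(length(u)))
  if (length(u) == 1) drop(out) else out
}

#' A detection bounding box
#'
#' @param bbox Numeric `c(u_min, v_min, u_max, v_max)`, pixels.
#' @param label Category name.
#' @param score Confidence in `[0, 1]`.
#' @return An object of class `detection`.
#' @export
detection <- function(bbox, label = "headland", score = 1) {
  bbox <- as.numeric(bbox)
  stopifnot(length(bbox) == 4, bbox[1] < bbox[3], bbox[2] < bbox[4],
            score >= 0, score <= 1)
  structure(list(bbox = bbox, label = label, score = score),
            class = "detection")
}

#' Localize a detection in 3D from a disparity (or depth) map
#'
#' The representative pixel is the bounding-box center (rounded to the pixel
#' grid). The depth is the median of the valid disparities in a core window
#' extending `floor(w/4)` columns and `floor(h/4)` rows on each side of the
#' center pixel (the central ~50% of the box, symmetric so that for depth
#' fields varying only with the image row the median equals the center-pixel
#' value exactly). The center pixel is then back-projected and expressed in
#' both camera and world frames.
#'
#' @param det A [detection()].
#' @param disp Disparity map: numeric matrix `[height, width]`, pixel (u, v)
#'   at `disp[v + 1, u + 1]`; values `<= 0` (or non-finite) are invalid.
#' @param s A [stereo_params()]; ignored when `is_depth = TRUE`.
#' @param K An [intrinsics()].
#' @param pose A [camera_pose()].
#' @param is_depth If TRUE, `disp` already holds metric depth (meters).
#' @return An object of class `localization3d` with elements `camera_point`,
#'   `world_point`, `source_pixel` (u, v), `depth_Zc`.
#' @export
locate_detection <- function(det, disp, s, K, pose, is_depth = FALSE) {
  stopifnot(inherits(det, "detection"), is.matrix(disp))
  b <- det$bbox
  if (b[1] < 0 || b[2] < 0 || b[3] > ncol(disp) - 1 || b[4] > nrow(disp) - 1) {
    stop("invalid-input: bbox extends outside the disparity map", call. = FALSE)
  }
  uc <- round((b[1] + b[3]) / 2)
  vc <- round((b[2] + b[4]) / 2)
  hu <- floor((b[3] - b[1]) / 4)
  hv <- floor((b[4] - b[2]) / 4)
  cols <- max(0, uc - hu):min(ncol(disp) - 1, uc + hu)
  rows <- max(0, vc - hv):min(nrow(disp) - 1, vc + hv)
  vals <- disp[rows + 1, cols + 1]
  vals <- vals[is.finite(vals) & vals > 0]
  if (length(vals) == 0) {
    stop("unlocalizable-detection: no valid disparity in the bbox core",
         call. = FALSE)
  }
  med <- stats::median(vals)
  Zc <- if (is_depth) med else depth_from_disparity(med, s)
  cam <- pixel_to_camera_3d(uc, vc, Zc, K)
  wld <- camera_to_world(cam, pose)
  structure(list(camera_point = unname(cam), world_point = unname(wld),
                 source_pixel = c(u = uc, v = vc), depth_Zc = Zc),
            class = "localization3d")
}

#' @export
print.localization3d <- function(x, ...) {
  cat(sprintf("localization3d: pixel (%g, %g), depth %.3f m\n",
              x$source_pixel[1], x$source_pixel[2], x$depth_Zc))
  cat(sprintf("  camera (%.3f, %.3f, %.3f)  world (%.3f, %.3f, %.3f)\n",
              x$camera_point[1], x$camera_point[2], x$camera_point[3],
              x$world_point[1], x$world_point[2], x$world_point[3]))
  invisible(x)
}

#' Localization error metrics
#'
#' Per-axis absolute differences, their Euclidean norm, and the relative
#' error (Euclidean error over the norm of the true position, in percent).
#' Everything is computed in full precision; round only for display.
#'
#' @param measured,actual Numeric 3-vectors, meters.
#' @return An object of class `localization_error` with `dX`, `dY`, `dZ`,
#'   `euclidean` (m) and `relative` (percent).
#' @examples
#' localization_error(c(1.010, 1.990, 0.990), c(1, 2, 1))
#' @export
localization_error <- function(measured, actual) {
  measured <- as.numeric(measured); actual <- as.numeric(actual)
  stopifnot(length(measured) == 3, length(actual) == 3,
            all(is.finite(measured)), all(is.finite(actual)))
  if (all(actual == 0)) {
    stop("undefined-relative-error: actual position is the origin",
         call. = FALSE)
  }
  d <- abs(measured - actual)
  euc <- sqrt(sum(d^2))
  structure(list(dX = d[1], dY = d[2], dZ = d[3], euclidean = euc,
                 relative = euc / sqrt(sum(actual^2)) * 100),
            class = "localization_error")
}

#' @export
print.localization_error <- function(x, ...) {
  cat(sprintf(
    "localization_error: dX=%.3f dY=%.3f dZ=%.3f  euclidean=%.3f m  relative=%.3f%%\n",
    x$dX, x$dY, x$dZ, x$euclidean, x$relative))
  invisible(x)
}
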