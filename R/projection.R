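#' Project a planned path into the image plane
#'
#' Each waypoint is transformed into the camera frame; points behind the
#' camera (`Zc <= 0`) are dropped and counted, the remainder are projected
#' through the intrinsics with the distortion model applied, and finally
#' clamped to the image boundary (clamped points are counted and flagged).
#'
#' @param path A [plan_turn()] result, or an n x 3 matrix of world points.
#' @param pose A [camera_pose()].
#' @param K An [intrinsics()].
#' @param dist Optional [distortion_model()].
#' @param which Use the `"smoothed"` spline samples (default) or the raw
#'   `"waypoints"` when `path` is a `planned_path`.
#' @return An object of class `projected_path`: `points` (data.frame `u`,
#'   `v`, `in_bounds`), `dropped_count`, `clamped_count`.
#' @export
project_path <- function(path, pose, K, dist = NULL,
                         which = c("smoothed", "waypoints")) {
  which <- match.arg(which)
  pts <- if (inherits(path, "planned_path")) {
    if (which == "smoothed") path$smoothed else path$waypoints
  } else {
    as_point_matrix(path)
  }
  stopifnot(nrow(pts) >= 1)
  cam <- world_to_camera(pts, pose)
  if (is.null(dim(cam))) cam <- matrix(cam, nrow = 1)
  keep <- cam[, 3] > 0
  dropped <- sum(!keep)
  if (!any(keep)) {
    stop("path-not-visible: every waypoint lies behind the camera",
         call. = FALSE)
  }
  uv <- project_to_pixel(cam[keep, , drop = FALSE], K, dist)
  if (is.null(dim(uv))) uv <- matrix(uv, nrow = 1)
  clamped <- clamp_to_image(uv, K)
  structure(list(points = clamped,
                 dropped_count = dropped,
                 clamped_count = sum(!clamped$in_bounds)),
            class = "projected_path")
}

#' @export
print.projected_path <- function(x, ...) {
  cat(sprintf("projected_path: %d point(s), %d dropped (behind camera), %d clamped\n",
              nrow(x$points), x$dropped_count, x$clamped_count))
  invisible(x)
}

# Paint a filled disc on an RGB array; clips at the image border.
paint_disc <- function(img, u, v, radius, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  uc <- round(u); vc <- round(v)
  du <- seq(-radius, radius)
  off <- expand.grid(du = du, dv = du)
  off <- off[off$du^2 + off$dv^2 <= radius^2, ]
  uu <- uc + off$du; vv <- vc + off$dv
  ok <- uu >= 0 & uu < w & vv >= 0 & vv < h
  if (!any(ok)) return(img)
  for (ch in 1:3) {
    img[cbind(vv[ok] + 1, uu[ok] + 1, ch)] <- color[ch]
  }
  img
}

#' Draw a projected path on an image
#'
#' Marks each retained projected point with a filled disc; the input image is
#' left unmodified (a painted copy is returned).
#'
#' @param image RGB array `[height, width, 3]` in `[0, 1]`.
#' @param proj A [project_path()] result (or a data.frame with `u`, `v`).
#' @param radius Disc radius in pixels (default 3).
#' @param color RGB triple in `[0, 1]` (default green).
#' @return The painted RGB array.
#' @export
draw_path <- function(image, proj, radius = 3, color = c(0, 1, 0)) {
  stopifnot(length(dim(image)) == 3)
  pts <- if (inherits(proj, "projected_path")) proj$points else proj
  if (is.null(pts) || nrow(pts) == 0) return(image)
  out <- image
  for (k in seq_len(nrow(pts))) {
    out <- paint_disc(out, pts$u[k], pts$v[k], radius, color)
  }
  out
}

#' Draw a line segment on an image
#'
#' Utility for debug overlays (fitted and standard lines). Dense sampling of
#' the segment painted with small discs.
#'
#' @param image RGB array.
#' @param p1,p2 Segment endpoints `c(u, v)`.
#' @param color RGB triple.
#' @param thickness Half-width in pixels.
#' @return The painted RGB array.
#' @export
draw_segment <- function(image, p1, p2, color = c(1, 1, 0), thickness = 1) {
  n <- max(2, ceiling(sqrt(sum((p2 - p1)^2))))
  us <- seq(p1[1], p2[1], length.out = n)
  vs <- seq(p1[2], p2[2], length.out = n)
  out <- image
  for (k in seq_len(n)) {
    out <- paint_disc(out, us[k], vs[k], thickness, color)
  }
  out
}
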