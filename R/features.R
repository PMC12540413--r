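#' Build horizontal ROI strips
#'
#' Full-width horizontal bands of fixed height laid from the top of the image
#' at a fixed vertical interval; strips that would extend past the bottom
#' edge are dropped.
#'
#' @param image_height Image height, pixels.
#' @param strip_height Strip height, pixels (default 40).
#' @param interval Vertical offset between consecutive strip tops (default 60).
#' @return A data.frame with columns `index`, `y_top`, `height`.
#' @examples
#' build_strips(480)  # 8 strips at y_top 0, 60, ..., 420
#' @export
build_strips <- function(image_height, strip_height = 40, interval = 60) {
  stopifnot(interval > 0, strip_height > 0)
  if (strip_height > image_height) {
    stop("invalid-geometry: strip_height exceeds image height", call. = FALSE)
  }
  y_top <- seq(0, image_height - strip_height, by = interval)
  data.frame(index = seq_along(y_top), y_top = y_top, height = strip_height)
}

#' Intersect one ROI strip with a filled contour mask
#'
#' Pixelwise AND of the strip band with the contour mask, split into
#' connected components (a strip can cross a fragmented row more than once).
#'
#' @param strip One row of [build_strips()] output (list or data.frame row).
#' @param contour_mask Binary matrix `[height, width]` (a filled contour).
#' @return A list of intersection regions, each a list with `strip_index`,
#'   `area` (px^2) and `pixels` (n x 2 matrix of u, v coordinates).
#' @export
intersect_strip <- function(strip, contour_mask) {
  stopifnot(is.matrix(contour_mask))
  y0 <- strip$y_top; h <- strip$height
  if (y0 < 0 || y0 + h > nrow(contour_mask)) {
    stop("invalid-input: strip does not fit the mask", call. = FALSE)
  }
  band <- contour_mask[(y0 + 1):(y0 + h), , drop = FALSE]
  if (!any(band > 0)) return(list())
  labels <- as.matrix(EBImage::bwlabel(band))
  n <- max(labels)
  out <- vector("list", n)
  for (id in seq_len(n)) {
    idx <- which(labels == id, arr.ind = TRUE)
    out[[id]] <- list(strip_index = strip$index,
                      area = nrow(idx),
                      pixels = cbind(u = idx[, 2] - 1, v = idx[, 1] - 1 + y0))
  }
  out
}

#' Screen intersection regions by area
#'
#' Removes regions whose area falls below `min_area`; order is preserved and
#' the operation is idempotent.
#'
#' @param regions List of intersection regions (see [intersect_strip()]).
#' @param min_area Minimum area in px^2 (default 50).
#' @return The filtered list.
#' @export
screen_regions <- function(regions, min_area = 50) {
  stopifnot(min_area >= 0)
  Filter(function(r) r$area >= min_area, regions)
}

#' Centroid (center of mass) of an intersection region
#'
#' Binary-weighted centroid: the mean of the member pixel coordinates, at
#' sub-pixel precision.
#'
#' @param region One intersection region.
#' @return Named numeric `c(Cx, Cy)`.
#' @export
region_centroid <- function(region) {
  if (is.null(region$pixels) || nrow(region$pixels) == 0) {
    stop("invalid-region: empty region has no centroid", call. = FALSE)
  }
  c(Cx = mean(region$pixels[, 1]), Cy = mean(region$pixels[, 2]))
}

#' Extract centerline feature points for every contour
#'
#' Lays the ROI strips over each filled contour, screens small intersections,
#' and records each surviving region's centroid, grouped by contour for
#' per-row line fitting.
#'
#' @param contours A [extract_contours()] result.
#' @param strips [build_strips()] output (defaults derived from the mask).
#' @param min_region_area Screening threshold in px^2.
#' @return A data.frame with columns `contour_id`, `strip_index`, `Cx`, `Cy`,
#'   `area`.
#' @export
extract_feature_points <- function(contours, strips = NULL,
                                   min_region_area = 50) {
  stopifnot(inherits(contours, "contour_set"))
  rows <- list()
  for (ct in contours$contours) {
    if (is.null(strips)) strips <- build_strips(nrow(ct$mask))
    for (k in seq_len(nrow(strips))) {
      regs <- intersect_strip(strips[k, ], ct$mask)
      regs <- screen_regions(regs, min_region_area)
      for (r in regs) {
        cen <- region_centroid(r)
        rows[[length(rows) + 1]] <- data.frame(
          contour_id = ct$id, strip_index = r$strip_index,
          Cx = cen[["Cx"]], Cy = cen[["Cy"]], area = r$area)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contour_id = integer(), strip_index = integer(),
                      Cx = numeric(), Cy = numeric(), area = numeric()))
  }
  do.call(rbind, rows)
}
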