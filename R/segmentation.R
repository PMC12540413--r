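#' HSV thresholds for vegetation masking
#'
#' Hue in degrees on `[0, 360)`, saturation and value on `[0, 1]`. The
#' defaults bracket the green of healthy soybean canopy while excluding soil,
#' straw and most shadow.
#'
#' @param h_min,h_max Hue bounds, degrees.
#' @param s_min,s_max Saturation bounds.
#' @param v_min,v_max Value bounds.
#' @return An object of class `hsv_thresholds`.
#' @export
hsv_thresholds <- function(h_min = 70, h_max = 170,
                           s_min = 0.25, s_max = 1,
                           v_min = 0.20, v_max = 1) {
  stopifnot(h_min < h_max, s_min < s_max, v_min < v_max,
            h_min >= 0, h_max < 360,
            s_min >= 0, s_max <= 1, v_min >= 0, v_max <= 1)
  structure(list(h_min = h_min, h_max = h_max, s_min = s_min, s_max = s_max,
                 v_min = v_min, v_max = v_max), class = "hsv_thresholds")
}

#' Binary vegetation mask from HSV thresholding
#'
#' A pixel is set iff its HSV triple lies inside the threshold box.
#'
#' @param image RGB array `[height, width, 3]`, values in `[0, 1]`.
#' @param th An [hsv_thresholds()].
#' @return Binary matrix `[height, width]` with values in `{0, 1}`.
#' @export
green_mask <- function(image, th = hsv_thresholds()) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3 || any(dim(image)[1:2] < 1)) {
    stop("invalid-input: expected a non-empty [H, W, 3] RGB array",
         call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]),
                            maxColorValue = 1)
  hue <- hsv[1, ] * 360
  inside <- hue >= th$h_min & hue <= th$h_max &
    hsv[2, ] >= th$s_min & hsv[2, ] <= th$s_max &
    hsv[3, ] >= th$v_min & hsv[3, ] <= th$v_max
  matrix(as.numeric(inside), nrow = h, ncol = w)
}

#' Staged morphological-opening schedule
#'
#' For each index `i` (in order) an erosion with a `(6-i) x (6-i)` rectangular
#' structuring element is followed by a dilation with an `(i) x (i)` element.
#' The default `i in {1, 3, 5}` runs three openings whose erosion kernels
#' shrink (5, 3, 1) while the dilation kernels grow (1, 3, 5): early passes
#' remove speckle, late passes reconnect fragmented row segments.
#'
#' @param iterations Ordered integer indices; every `6 - i` and `i` must be
#'   at least 1.
#' @return An object of class `morphology_schedule`.
#' @export
morphology_schedule <- function(iterations = c(1, 3, 5)) {
  it <- as.integer(iterations)
  if (length(it) < 1 || any(it < 1) || any(6 - it < 1)) {
    stop("invalid-schedule: kernel dimensions must be >= 1", call. = FALSE)
  }
  structure(list(iterations = it,
                 erosion_kernels = 6L - it,
                 dilation_kernels = it),
            class = "morphology_schedule")
}

# Binary erosion/dilation with a k x k box element; pixels outside the image
# are treated as background (0). EBImage replicates the border, so pad first.
morph_box <- function(mask, k, op = c("erode", "dilate")) {
  op <- match.arg(op)
  if (k <= 1) return(mask)
  r <- k %/% 2
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2 * r, w + 2 * r)
  padded[(r + 1):(r + h), (r + 1):(r + w)] <- mask
  kern <- matrix(1, k, k)
  out <- if (op == "erode") EBImage::erode(padded, kern)
         else EBImage::dilate(padded, kern)
  out <- as.matrix(out)[(r + 1):(r + h), (r + 1):(r + w)]
  (out > 0) + 0
}

#' Apply the morphological-opening schedule to a binary mask
#'
#' @param mask Binary matrix `[height, width]`.
#' @param sched A [morphology_schedule()].
#' @return Binary matrix of the same size.
#' @export
open_schedule <- function(mask, sched = morphology_schedule()) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  for (i in sched$iterations) {
    mask <- morph_box(mask, 6L - i, "erode")
    mask <- morph_box(mask, i, "dilate")
  }
  mask
}

#' Default minimum contour area, scaled with image size
#'
#' 500 px^2 at 640 x 480, scaled by `(W * H) / (640 * 480)`.
#'
#' @param width,height Image size in pixels.
#' @return Area threshold in px^2.
#' @export
default_min_contour_area <- function(width, height) {
  500 * (width * height) / (640 * 480)
}

#' Extract filled contours from a binary mask
#'
#' Holes are filled, connected components labelled, and components with area
#' below `min_area` discarded. Each retained contour carries its filled
#' component mask (used downstream for ROI intersection) and its boundary
#' polygon in (u, v) pixel coordinates.
#'
#' @param mask Binary matrix `[height, width]`.
#' @param min_area Minimum component area in px^2; defaults to
#'   [default_min_contour_area()] for the mask's size.
#' @return An object of class `contour_set`: list with `contours` (each a
#'   list `id`, `area`, `mask`, `polygon`) and `min_area`.
#' @export
extract_contours <- function(mask, min_area = NULL) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  if (is.null(min_area)) {
    min_area <- default_min_contour_area(ncol(mask), nrow(mask))
  }
  stopifnot(min_area >= 0)
  filled <- as.matrix(EBImage::fillHull(mask))
  labels <- as.matrix(EBImage::bwlabel(filled))
  n <- max(labels)
  contours <- list()
  if (n > 0) {
    areas <- tabulate(labels[labels > 0], nbins = n)
    keep <- which(areas >= min_area)
    # order left to right by component centroid column for stable row ids
    if (length(keep) > 0) {
      cx <- vapply(keep, function(id) mean(which(labels == id, arr.ind = TRUE)[, 2]),
                   numeric(1))
      keep <- keep[order(cx)]
    }
    oc <- EBImage::ocontour(labels)
    for (j in seq_along(keep)) {
      id <- keep[j]
      cmask <- (labels == id) + 0
      # ocontour is computed on the transposed layout: x -> matrix row (v),
      # y -> matrix column (u); convert to (u, v) pixel coordinates
      poly <- oc[[id]]
      contours[[j]] <- list(id = j, area = areas[id], mask = cmask,
                            polygon = cbind(u = poly[, 2], v = poly[, 1]))
    }
  }
  structure(list(contours = contours, min_area = min_area),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set: %d contour(s), min_area=%.0f px^2\n",
              length(x$contours), x$min_area))
  for (ct in x$contours) {
    cat(sprintf("  #%d area=%d px^2\n", ct$id, ct$area))
  }
  invisible(x)
}

#' @export
length.contour_set <- function(x) length(x$contours)
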