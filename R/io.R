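#' Read an RGB image
#'
#' PNG via the png package; JPEG/TIFF via EBImage. Grayscale images are
#' replicated to three channels; an alpha channel is dropped.
#'
#' @param path Image file path.
#' @return RGB array `[height, width, 3]` in `[0, 1]`.
#' @export
read_image_rgb <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    eb <- EBImage::readImage(path)
    img <- aperm(EBImage::imageData(eb), c(2, 1, 3)[seq_along(dim(eb))])
  }
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image as PNG
#'
#' @param image RGB array `[height, width, 3]` in `[0, 1]`.
#' @param path Output path.
#' @export
write_image_rgb <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a disparity or depth map
#'
#' Supported: plain-text TSV matrices (as written by [write_disparity()]),
#' single-channel float TIFF, and PNG (values rescaled from `[0, 1]` by
#' `scale`).
#'
#' @param path File path.
#' @param scale Multiplier applied to PNG-encoded values (default 1).
#' @return Numeric matrix `[height, width]`.
#' @export
read_disparity <- function(path, scale = 1) {
  stopifnot(file.exists(path))
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    m <- as.matrix(utils::read.table(path, sep = "\t"))
    dimnames(m) <- NULL
    m
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * scale
  } else {
    stop("unsupported disparity format: ", path, call. = FALSE)
  }
}

#' Write a disparity or depth map as a plain-text TSV matrix
#'
#' Full double precision is preserved; the format is portable and
#' deterministic.
#'
#' @param disp Numeric matrix.
#' @param path Output path (conventionally `.tsv`).
#' @export
write_disparity <- function(disp, path) {
  utils::write.table(format(disp, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read detections from a JSON file
#'
#' Expects a JSON list of objects `{label, score, bbox: [u_min, v_min,
#' u_max, v_max]}`.
#'
#' @param path JSON file path.
#' @return A list of [detection()] objects.
#' @export
read_detections <- function(path) {
  stopifnot(file.exists(path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(d) {
    detection(bbox = as.numeric(unlist(d$bbox)),
              label = d$label %||% "headland",
              score = d$score %||% 1)
  })
}

#' Write detections to a JSON file
#'
#' @param dets List of [detection()] objects.
#' @param path Output path.
#' @export
write_detections <- function(dets, path) {
  jsonlite::write_json(
    lapply(dets, function(d) list(label = d$label, score = d$score,
                                  bbox = d$bbox)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
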