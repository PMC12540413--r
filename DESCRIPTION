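Package: headturn
Title: Headland Turn Path Planning and Visualization for Row Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Vision pipeline for visualizing headland turning paths in ridge-planted
    row crops such as soybean. Segments green crop rows in RGB field images by HSV
    thresholding and a staged morphological opening, extracts per-row centerline
    feature points from horizontal region-of-interest strips, fits row centerlines
    by total least squares and measures their orientation, lifts detected headland
    bounding boxes to 3D world coordinates from stereo disparity, plans a circular
    arc steering path smoothed by a natural cubic spline, and projects the path
    back onto the image plane. Includes a seeded synthetic field-scene generator
    with exact ground truth (crop masks, standard lines, depth maps, headland
    positions) so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    withr,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
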