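# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

# The stratified 20-scene suite used by the recovery tests; built once per run.
fixture_suite <- function() {
  if (is.null(.fixture_cache$suite)) {
    .fixture_cache$suite <- make_fixture_suite(20, base_seed = 7)
  }
  .fixture_cache$suite
}

# A single clutter-free scene (exactly three clean row bands).
clean_scene <- function(seed = 11, azimuth = 90, ...) {
  cl <- clutter_preset("none")
  render_scene(scene_config(row_azimuth_deg = azimuth,
                            straw_density = cl$straw_density,
                            shadow_strength = cl$shadow_strength,
                            missing_prob = cl$missing_prob,
                            seed = seed, ...))
}

# Term-by-term scalar evaluation of the radial-tangential distortion model,
# written independently of distort_normalized().
oracle_distort <- function(x, y, k1, k2, p1, p2, k3) {
  r2 <- x * x + y * y
  rad <- 1 + k1 * r2 + k2 * r2 * r2 + k3 * r2 * r2 * r2
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x * x)
  yd <- y * rad + p1 * (r2 + 2 * y * y) + 2 * p2 * x * y
  c(xd, yd)
}

# Naive double-loop binary morphology with a k x k box element and
# outside-the-image treated as 0 (the border convention under test).
oracle_morph <- function(mask, k, op) {
  r <- k %/% 2
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- max(1, i - r):min(h, i + r)
      rj <- max(1, j - r):min(w, j + r)
      win <- mask[ri, rj]
      n_out <- k * k - length(win)  # pixels outside the image, all 0
      out[i, j] <- if (op == "erode") {
        as.numeric(all(win == 1) && n_out == 0)
      } else {
        as.numeric(any(win == 1))
      }
    }
  }
  out
}

# Brute-force total-least-squares orientation: scan the angle minimizing the
# perpendicular sum of squares through the centroid.
oracle_tls_angle <- function(pts, step = 0.01) {
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  angles <- seq(0, 180 - step, by = step)
  sse <- vapply(angles, function(a) {
    th <- a * pi / 180
    nrm <- c(-sin(th), cos(th))  # unit normal of a line at angle a
    sum((d %*% nrm)^2)
  }, numeric(1))
  angles[which.min(sse)]
}

# The 3D-localization evaluation table bundled with the package.
localization_pairs <- function() {
  utils::read.csv(system.file("extdata", "localization_eval_points.csv",
                              package = "headturn"))
}

angular_samples <- function() {
  utils::read.csv(system.file("extdata", "angular_deviation_samples.csv",
                              package = "headturn"))
}
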