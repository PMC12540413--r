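# Vectorized HSV -> RGB (h in degrees [0,360), s, v in [0,1]).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i %% 6
  sel <- idx == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- idx == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- idx == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- idx == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- idx == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- idx == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  cbind(r, g, b)
}

#' Clutter presets for the synthetic scene generator
#'
#' @param level `"none"`, `"low"`, `"medium"` or `"high"`.
#' @return A list with `straw_density` (streak count), `shadow_strength`
#'   (`[0, 1]` brightness loss across the frame) and `missing_prob`
#'   (per-plant dropout probability).
#' @export
clutter_preset <- function(level = c("medium", "none", "low", "high")) {
  level <- match.arg(level)
  switch(level,
         none = list(straw_density = 0, shadow_strength = 0, missing_prob = 0),
         low = list(straw_density = 2, shadow_strength = 0.10, missing_prob = 0.02),
         medium = list(straw_density = 8, shadow_strength = 0.30, missing_prob = 0.08),
         high = list(straw_density = 15, shadow_strength = 0.45, missing_prob = 0.20))
}

#' Synthetic field-scene configuration
#'
#' Emulates a ridge-planted soybean field: three rows on a ridge platform
#' (base 1.100 m, platform 0.700 m, height 0.250 m, rows on the platform
#' centerline and offset 0.225 m to each side) viewed by a camera 2 m above
#' the ground pitched 30 degrees toward it. Rows run at a configurable
#' azimuth in the ground plane and terminate at a bare headland band. Plant
#' canopies are modelled as overlapping green ellipses on the ground plane
#' (plant height is neglected for depth); straw streaks, a brightness
#' gradient (shadow) and missing plants provide clutter.
#'
#' @param row_azimuth_deg Ground-truth row azimuth, degrees (90 = straight
#'   ahead along Z).
#' @param ridge_base_width,platform_width,ridge_height Ridge geometry, m.
#' @param row_offset Lateral offset of the outer rows from the platform
#'   centerline, m.
#' @param camera_height Camera height above ground, m.
#' @param camera_pitch Downward pitch of the optical axis, degrees.
#' @param plant_spacing,plant_radius In-row plant spacing and canopy
#'   half-width, m.
#' @param row_start_z,headland_z Along-track world Z where rows begin and
#'   where they terminate into the headland, m.
#' @param headland_depth Depth of the bare headland band, m.
#' @param straw_density Number of straw streaks.
#' @param shadow_strength Brightness loss of the shadow gradient, `[0, 1)`.
#' @param missing_prob Per-plant dropout probability, `[0, 1]`.
#' @param f,B Stereo focal length (px) and baseline (m).
#' @param fx,fy,cx,cy,width,height Camera intrinsics.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(row_azimuth_deg = 90,
                         ridge_base_width = 1.100, platform_width = 0.700,
                         ridge_height = 0.250, row_offset = 0.225,
                         camera_height = 2.0, camera_pitch = 30,
                         plant_spacing = 0.10, plant_radius = 0.07,
                         row_start_z = 1.2, headland_z = 4.0,
                         headland_depth = 1.2,
                         straw_density = 8, shadow_strength = 0.30,
                         missing_prob = 0.08,
                         f = 400, B = 0.075,
                         fx = 400, fy = 400, cx = 320, cy = 240,
                         width = 640, height = 480,
                         seed = 1L) {
  stopifnot(ridge_base_width > 0, platform_width > 0, ridge_height > 0,
            row_offset > 0, camera_height > 0, plant_spacing > 0,
            plant_radius > 0, headland_depth > 0, row_start_z < headland_z,
            missing_prob >= 0, missing_prob <= 1,
            shadow_strength >= 0, shadow_strength < 1,
            straw_density >= 0, f > 0, B > 0)
  structure(as.list(environment()), class = "scene_config")
}

#' Render a synthetic field scene with exact ground truth
#'
#' Produces the RGB image, the dense disparity map (from exact ray-ground
#' intersection: `d = f B / Zc`, 0 where the ray misses the ground), and a
#' truth record: the per-pixel crop mask, per-row standard lines (projected
#' row endpoints, i.e. the midpoints of each row's near and far edge), their
#' image orientations, the headland bounding box, and the headland's world
#' position with its depth.
#'
#' The camera pose used for rendering is `camera_pose(-camera_pitch,
#' c(0, camera_height, 0))`: the negated pitch points the optical axis at
#' the ground under the frame conventions of [rotation_about_x()].
#'
#' @param cfg A [scene_config()].
#' @return An object of class `field_scene`: `image` (`[H, W, 3]`),
#'   `disparity` (`[H, W]`), `truth` (list), `config`, plus the `camera`
#'   list (intrinsics, pose, stereo) used.
#' @export
render_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  withr::with_seed(cfg$seed, render_scene_impl(cfg))
}

render_scene_impl <- function(cfg) {
  K <- intrinsics(cfg$fx, cfg$fy, cfg$cx, cfg$cy, cfg$width, cfg$height)
  pose <- camera_pose(gamma = -cfg$camera_pitch, T = c(0, cfg$camera_height, 0))
  s <- stereo_params(cfg$f, cfg$B)
  W <- K$width; H <- K$height
  npix <- W * H

  # per-pixel ground intersection (rays through pixel centers)
  u <- rep(0:(W - 1), each = H)     # column-major over [H, W] matrices
  v <- rep(0:(H - 1), times = W)
  xn <- (u - K$cx) / K$fx
  yn <- (v - K$cy) / K$fy
  Rinv <- t(rotation_about_x(pose$gamma))
  dwx <- xn
  dwy <- Rinv[2, 2] * yn + Rinv[2, 3]
  dwz <- Rinv[3, 2] * yn + Rinv[3, 3]
  ground <- dwy < -1e-9
  t_hit <- ifelse(ground, -pose$T[2] / dwy, NA_real_)
  Xw <- t_hit * dwx
  Zw <- t_hit * dwz
  depth <- t_hit  # Zc equals t because the camera-frame ray has unit Z

  # row-frame coordinates: along/lateral relative to the ridge centerline
  az <- cfg$row_azimuth_deg * pi / 180
  z_pivot <- (cfg$row_start_z + cfg$headland_z) / 2
  dx <- cos(az); dz <- sin(az)
  along <- Xw * dx + (Zw - z_pivot) * dz
  lateral <- -Xw * dz + (Zw - z_pivot) * dx
  a_min <- cfg$row_start_z - z_pivot
  a_max <- cfg$headland_z - z_pivot

  # plant presence per (row, plant index), with dropout
  offsets <- c(-cfg$row_offset, 0, cfg$row_offset)
  jmin <- floor(a_min / cfg$plant_spacing)
  jmax <- ceiling(a_max / cfg$plant_spacing)
  nj <- jmax - jmin + 1
  present <- matrix(stats::runif(3 * nj) >= cfg$missing_prob, nrow = 3)

  crop <- rep(FALSE, npix)
  # canopy half-length along the row: neighbouring canopies overlap (the
  # in-row canopy closes early in soybean), so a single missing plant thins
  # the row without severing it
  ral <- cfg$plant_spacing * 1.0
  in_span <- ground & along >= a_min & along <= a_max
  for (k in 1:3) {
    lat_k <- lateral - offsets[k]
    near <- in_span & abs(lat_k) <= cfg$plant_radius
    if (!any(near)) next
    j <- round(along[near] / cfg$plant_spacing)
    j <- pmin(pmax(j, jmin), jmax)
    da <- along[near] - j * cfg$plant_spacing
    hit <- (da / ral)^2 + (lat_k[near] / cfg$plant_radius)^2 <= 1
    hit <- hit & present[k, j - jmin + 1]
    idx <- which(near)[hit]
    crop[idx] <- TRUE
  }

  headland <- ground & along > a_max & along <= a_max + cfg$headland_depth &
    abs(lateral) <= cfg$ridge_base_width / 2

  # colors: soil everywhere on the ground, straw streaks, then plants on top
  hh <- stats::runif(npix, 17, 33)
  ss <- stats::runif(npix, 0.35, 0.55)
  vv <- stats::runif(npix, 0.32, 0.48)

  if (cfg$straw_density > 0) {
    n_straw <- cfg$straw_density
    scx <- stats::runif(n_straw, -1.6, 1.6)
    scz <- stats::runif(n_straw, cfg$row_start_z - 0.4,
                        cfg$headland_z + cfg$headland_depth)
    sang <- stats::runif(n_straw, 0, pi)
    slen <- stats::runif(n_straw, 0.2, 0.5)
    swid <- stats::runif(n_straw, 0.015, 0.03)
    for (iS in seq_len(n_straw)) {
      ex <- cos(sang[iS]) * slen[iS] / 2
      ez <- sin(sang[iS]) * slen[iS] / 2
      # distance from (Xw, Zw) to the straw segment
      px <- Xw - scx[iS]; pz <- Zw - scz[iS]
      tt <- pmin(pmax((px * ex + pz * ez) / (ex^2 + ez^2), -1), 1)
      d2 <- (px - tt * ex)^2 + (pz - tt * ez)^2
      on_straw <- ground & !is.na(d2) & d2 <= swid[iS]^2
      if (any(on_straw)) {
        hh[on_straw] <- stats::runif(sum(on_straw), 42, 54)
        ss[on_straw] <- stats::runif(sum(on_straw), 0.25, 0.38)
        vv[on_straw] <- stats::runif(sum(on_straw), 0.62, 0.80)
      }
    }
  }

  if (any(crop)) {
    nc <- sum(crop)
    hh[crop] <- stats::runif(nc, 95, 140)
    ss[crop] <- stats::runif(nc, 0.55, 0.85)
    vv[crop] <- stats::runif(nc, 0.45, 0.80)
  }

  sky <- !ground
  if (any(sky)) {
    hh[sky] <- 210; ss[sky] <- 0.12; vv[sky] <- 0.88
  }

  rgb <- hsv_to_rgb(hh, ss, vv)
  if (cfg$shadow_strength > 0) {
    g <- 0.5 * (u / (W - 1)) + 0.5 * (v / (H - 1))
    rgb <- rgb * (1 - cfg$shadow_strength * g)
  }
  image <- array(0, c(H, W, 3))
  image[, , 1] <- rgb[, 1]; image[, , 2] <- rgb[, 2]; image[, , 3] <- rgb[, 3]

  disparity <- matrix(0, H, W)
  disparity[cbind(v + 1, u + 1)[ground, ]] <- s$f * s$B / depth[ground]

  crop_mask <- matrix(0, H, W)
  crop_mask[cbind(v + 1, u + 1)[crop, ]] <- 1

  # truth rows: project the row-axis endpoints (standard-line construction)
  rows <- list()
  for (k in 1:3) {
    wA <- c(dx * a_min - dz * offsets[k], 0,
            z_pivot + dz * a_min + dx * offsets[k])
    wB <- c(dx * a_max - dz * offsets[k], 0,
            z_pivot + dz * a_max + dx * offsets[k])
    pA <- project_to_pixel(world_to_camera(wA, pose), K)
    pB <- project_to_pixel(world_to_camera(wB, pose), K)
    sl <- standard_line(pA[1], pA[2], pB[1], pB[2])
    rows[[k]] <- list(id = k, world_start = wA, world_end = wB,
                      p_near = unname(pA), p_far = unname(pB),
                      standard = sl, orientation_deg = sl$beta_deg)
  }

  # headland truth: bbox of the band's pixel support; target = ground point
  # under the bbox-center ray (computed analytically, not from the map)
  hl_idx <- which(headland)
  stopifnot(length(hl_idx) > 0)
  hu <- u[hl_idx]; hv <- v[hl_idx]
  bbox <- c(min(hu), min(hv), max(hu), max(hv))
  uc <- round((bbox[1] + bbox[3]) / 2)
  vc <- round((bbox[2] + bbox[4]) / 2)
  xnc <- (uc - K$cx) / K$fx; ync <- (vc - K$cy) / K$fy
  dyc <- Rinv[2, 2] * ync + Rinv[2, 3]
  dzc <- Rinv[3, 2] * ync + Rinv[3, 3]
  tc <- -pose$T[2] / dyc
  target_world <- c(tc * xnc, 0, tc * dzc)
  truth <- list(
    rows = rows,
    crop_mask = crop_mask,
    headland = list(bbox = bbox, center_pixel = c(uc, vc),
                    world = target_world, depth_Zc = tc),
    azimuth_deg = cfg$row_azimuth_deg,
    seed = cfg$seed)

  structure(list(image = image, disparity = disparity, truth = truth,
                 config = cfg,
                 camera = list(intrinsics = K, pose = pose, stereo = s,
                               distortion = distortion_model())),
            class = "field_scene")
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("field_scene: %dx%d, azimuth %.1f deg, seed %d\n",
              dim(x$image)[2], dim(x$image)[1], x$truth$azimuth_deg,
              x$truth$seed))
  cat(sprintf("  headland bbox (%d, %d, %d, %d), target (%.3f, %.3f, %.3f) m\n",
              x$truth$headland$bbox[1], x$truth$headland$bbox[2],
              x$truth$headland$bbox[3], x$truth$headland$bbox[4],
              x$truth$headland$world[1], x$truth$headland$world[2],
              x$truth$headland$world[3]))
  invisible(x)
}

#' Generate a stratified suite of synthetic scenes
#'
#' Scenes span row azimuths across `azimuth_range` and cycle through low,
#' medium and high clutter. With `dir` set, each scene is written to
#' `scene_NNN/` as `image.png`, `disparity.tsv` and `truth.json`; scenes are
#' always also returned in memory.
#'
#' @param n Number of scenes (>= 1).
#' @param base_seed Integer; scene i uses seed `base_seed + i`.
#' @param dir Optional output directory.
#' @param azimuth_range Degrees, default `c(60, 120)`.
#' @param ... Further arguments passed to [scene_config()].
#' @return A list of `field_scene` objects with an attribute
#'   `clutter_levels` (character vector).
#' @export
make_fixture_suite <- function(n = 20, base_seed = 7, dir = NULL,
                               azimuth_range = c(60, 120), ...) {
  stopifnot(n >= 1)
  az <- if (n == 1) mean(azimuth_range) else
    seq(azimuth_range[1], azimuth_range[2], length.out = n)
  levels <- rep(c("low", "medium", "high"), length.out = n)
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- clutter_preset(levels[i])
    cfg <- scene_config(row_azimuth_deg = az[i],
                        straw_density = cl$straw_density,
                        shadow_strength = cl$shadow_strength,
                        missing_prob = cl$missing_prob,
                        seed = base_seed + i, ...)
    scenes[[i]] <- render_scene(cfg)
    if (!is.null(dir)) {
      write_scene(scenes[[i]], file.path(dir, sprintf("scene_%03d", i)),
                  clutter = levels[i])
    }
  }
  attr(scenes, "clutter_levels") <- levels
  scenes
}

#' Write a rendered scene to a directory
#'
#' @param scene A `field_scene`.
#' @param dir Output directory (created if needed).
#' @param clutter Optional clutter label echoed into the truth file.
#' @return The directory path, invisibly.
#' @export
write_scene <- function(scene, dir, clutter = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_rgb(scene$image, file.path(dir, "image.png"))
  write_disparity(scene$disparity, file.path(dir, "disparity.tsv"))
  tr <- scene$truth
  out <- list(
    rows = lapply(tr$rows, function(r) list(
      id = r$id, world_start = r$world_start, world_end = r$world_end,
      p_near = r$p_near, p_far = r$p_far,
      orientation_deg = r$orientation_deg)),
    headland = tr$headland,
    azimuth_deg = tr$azimuth_deg,
    clutter = clutter,
    seed = tr$seed,
    config = scene$config[setdiff(names(scene$config), character(0))])
  jsonlite::write_json(out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_image_rgb(array(rep(tr$crop_mask, 3),
                        c(dim(tr$crop_mask), 3)),
                  file.path(dir, "crop_mask.png"))
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir Scene directory.
#' @return A list with `image`, `disparity`, `truth` (as plain lists).
#' @export
read_scene <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(image = read_image_rgb(file.path(dir, "image.png")),
       disparity = read_disparity(file.path(dir, "disparity.tsv")),
       truth = truth)
}
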