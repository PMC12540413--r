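#' Default pipeline configuration
#'
#' Nested list with the documented defaults for every stage: `camera`
#' (intrinsics, distortion, pose, stereo), `segmentation` (HSV bounds,
#' opening schedule, minimum contour area), `features` (strip geometry and
#' screening area), `planner` (minimum radius, sample count, lateral offset
#' of the turn target) and `io` (overlay styling).
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    camera = list(fx = 400, fy = 400, cx = 320, cy = 240,
                  width = 640, height = 480,
                  distortion = c(0, 0, 0, 0, 0),
                  gamma_deg = 30, T = c(0, 2, 0),
                  stereo_f = 400, stereo_b = 0.075),
    segmentation = list(h_min = 70, h_max = 170, s_min = 0.25, s_max = 1,
                        v_min = 0.20, v_max = 1,
                        schedule = c(1, 3, 5),
                        min_contour_area = NULL),
    features = list(strip_height = 40, interval = 60, min_region_area = 50),
    planner = list(R_min = 1.5, n_samples = 100, turn_offset_x = 2.2),
    io = list(marker_radius = 3, overlay_color = c(0, 1, 0))
  )
}

check_config_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(ref)) {
      stop(sprintf("config-error: unknown key '%s%s'", path, nm),
           call. = FALSE)
    }
    if (is.list(cfg[[nm]]) && is.list(ref[[nm]]) &&
        !is.null(names(ref[[nm]]))) {
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML (or JSON) file, validates it strictly against the schema of
#' [default_config()] (unknown keys are rejected), and merges it over the
#' defaults.
#'
#' @param path Optional config file; NULL returns the defaults.
#' @return The merged configuration list.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  stopifnot(file.exists(path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  check_config_keys(user, cfg)
  merge_config(cfg, user)
}

#' Write a configuration back to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Heuristic headland detection from the crop-row mask
#'
#' Non-learned stand-in for a trained detector: finds the far end of the
#' crop-row support (the largest image row still containing crop pixels,
#' i.e. the greatest distance along the camera's forward direction under the
#' package's projection conventions) and proposes a bounding box spanning the
#' rows' columns in the band just beyond it.
#'
#' @param mask Cleaned binary crop mask.
#' @param band_px Height of the proposed box, pixels.
#' @param margin_px Gap between the last crop row and the box, pixels.
#' @param min_row_px Minimum crop pixels for an image row to count as
#'   row-bearing.
#' @return A [detection()] with label "headland".
#' @export
detect_headland_heuristic <- function(mask, band_px = 30, margin_px = 4,
                                      min_row_px = 5) {
  stopifnot(is.matrix(mask))
  prof <- rowSums(mask)
  rows_v <- which(prof >= min_row_px) - 1
  if (length(rows_v) == 0) {
    stop("unlocalizable-detection: no crop rows in the mask", call. = FALSE)
  }
  cols <- which(colSums(mask) > 0) - 1
  v0 <- min(max(rows_v) + margin_px, nrow(mask) - 2)
  v1 <- min(v0 + band_px, nrow(mask) - 1)
  detection(bbox = c(max(min(cols) - 10, 0), v0,
                     min(max(cols) + 10, ncol(mask) - 1), v1),
            label = "headland", score = 0.5)
}

#' Run the full headland-turn pipeline on one frame
#'
#' Stages: HSV segmentation, morphological opening, contour extraction, ROI
#' strip feature points, per-contour centerline fits, headland 3D
#' localization, arc planning, and projection of the planned path back onto
#' the image.
#'
#' @param image RGB array or path to an image file.
#' @param disparity Disparity matrix or path to a disparity file.
#' @param detections List of [detection()] objects, a path to a detections
#'   JSON, or NULL to use [detect_headland_heuristic()].
#' @param config Configuration list from [pipeline_config()].
#' @param out_dir Optional directory for artifacts (feature CSV, arc JSON,
#'   waypoint CSV, overlay PNG, projection side-car JSON).
#' @param camera_pose_override Optional [camera_pose()] replacing the pose in
#'   `config` (the synthetic scenes view the ground with a negated pitch).
#' @param allow_plan_failure If TRUE, an infeasible turn (or other planner
#'   error) leaves `plan`, `projection` and `overlay` NULL with the message in
#'   `plan_error` instead of aborting; the perception outputs are retained.
#' @return A list with `mask`, `opened`, `contours`, `features`, `lines`
#'   (one `fitted_line` per contour), `beta_deg` (azimuth used), `detection`,
#'   `localization`, `plan`, `projection`, `overlay`.
#' @export
run_pipeline <- function(image, disparity, detections = NULL,
                         config = default_config(), out_dir = NULL,
                         camera_pose_override = NULL,
                         allow_plan_failure = FALSE) {
  if (is.character(image)) image <- stage("input", read_image_rgb(image))
  if (is.character(disparity)) {
    disparity <- stage("input", read_disparity(disparity))
  }
  if (is.character(detections)) {
    detections <- stage("input", read_detections(detections))
  }
  cam <- camera_from_list(config$camera)
  if (!is.null(camera_pose_override)) cam$pose <- camera_pose_override
  seg <- config$segmentation

  th <- hsv_thresholds(seg$h_min, seg$h_max, seg$s_min, seg$s_max,
                       seg$v_min, seg$v_max)
  mask <- stage("segmentation", green_mask(image, th))
  opened <- stage("morphology",
                  open_schedule(mask, morphology_schedule(seg$schedule)))
  contours <- stage("contours", extract_contours(opened, seg$min_contour_area))
  if (length(contours$contours) == 0) {
    stop("stage 'contours' failed: no contours above the area threshold",
         call. = FALSE)
  }
  strips <- build_strips(nrow(mask), config$features$strip_height,
                         config$features$interval)
  features <- stage("features",
                    extract_feature_points(contours, strips,
                                           config$features$min_region_area))
  lines <- stage("centerline", {
    ids <- unique(features$contour_id)
    out <- list()
    for (id in ids) {
      pts <- features[features$contour_id == id, c("Cx", "Cy")]
      if (nrow(pts) >= 2) out[[as.character(id)]] <- fit_line(pts)
    }
    if (length(out) == 0) stop("no contour has enough feature points")
    out
  })

  # steering azimuth: centerline of the contour nearest the image center
  cxs <- vapply(lines, function(l) l$x0, numeric(1))
  central <- which.min(abs(cxs - cam$intrinsics$cx))
  beta_deg <- line_angle(lines[[central]])

  if (is.null(detections)) {
    detections <- list(stage("detection", detect_headland_heuristic(opened)))
  }
  loc <- stage("localization",
               locate_detection(detections[[1]], disparity, cam$stereo,
                                cam$intrinsics, cam$pose))

  plan <- proj <- overlay <- NULL
  plan_error <- NULL
  plan_expr <- function() {
    inp <- planner_input(Xw = loc$world_point[1] + config$planner$turn_offset_x,
                         Zw = loc$world_point[3],
                         beta_deg = beta_deg,
                         R_min = config$planner$R_min)
    plan_turn(inp, config$planner$n_samples)
  }
  if (allow_plan_failure) {
    plan <- tryCatch(plan_expr(), error = function(e) {
      plan_error <<- conditionMessage(e)
      NULL
    })
  } else {
    plan <- stage("planner", plan_expr())
  }
  if (!is.null(plan)) {
    proj <- stage("projection",
                  project_path(plan, cam$pose, cam$intrinsics, cam$distortion))
    overlay <- draw_path(image, proj, config$io$marker_radius,
                         config$io$overlay_color)
  }

  result <- list(mask = mask, opened = opened, contours = contours,
                 features = features, lines = lines, beta_deg = beta_deg,
                 detection = detections[[1]], localization = loc,
                 plan = plan, projection = proj, overlay = overlay,
                 plan_error = plan_error)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features,
                   file.path(out_dir, "feature_points.csv"),
                   row.names = FALSE)
  if (is.null(result$plan)) return(invisible(out_dir))
  spec <- result$plan$spec
  jsonlite::write_json(
    list(R = spec$R, O = spec$O, alpha_deg = spec$alpha,
         direction = spec$turn_direction,
         terminal_offset_m = result$plan$terminal_offset,
         beta_deg = result$beta_deg),
    file.path(out_dir, "arc_spec.json"), auto_unbox = TRUE, digits = NA)
  wp <- result$plan$waypoints
  utils::write.csv(data.frame(X = wp[, 1], Y = wp[, 2], Z = wp[, 3]),
                   file.path(out_dir, "waypoints.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_points = nrow(result$projection$points),
         dropped_count = result$projection$dropped_count,
         clamped_count = result$projection$clamped_count),
    file.path(out_dir, "projection.json"), auto_unbox = TRUE)
  write_image_rgb(result$overlay, file.path(out_dir, "overlay.png"))
  invisible(out_dir)
}

# u-coordinate of a fitted line at image row v (lines are near-vertical for
# rows seen along the camera axis).
line_u_at_v <- function(line, v) {
  if (abs(line$vy) < 1e-9) return(line$x0)
  line$x0 + (v - line$y0) * line$vx / line$vy
}

#' Score a pipeline run against a scene's ground truth
#'
#' Matches each truth row's standard line to the nearest fitted centerline
#' (by horizontal position at the row's mid-height) and computes signed
#' angular deviations; localizes the truth bounding box from the scene's
#' exact disparity map and compares with the recorded headland position.
#'
#' @param scene A `field_scene` from [render_scene()].
#' @param config Pipeline configuration.
#' @return A list with `deviations` (data.frame `row_id`, `theta`,
#'   `abs_theta`), `loc_error` (a [localization_error()]), `beta_deg` and
#'   the pipeline `result`.
#' @export
evaluate_scene <- function(scene, config = default_config()) {
  det <- detection(scene$truth$headland$bbox)
  result <- run_pipeline(scene$image, scene$disparity, list(det), config,
                         camera_pose_override = scene$camera$pose,
                         allow_plan_failure = TRUE)
  devs <- list()
  for (r in scene$truth$rows) {
    vmid <- (r$p_near[2] + r$p_far[2]) / 2
    target_u <- (r$p_near[1] + r$p_far[1]) / 2
    du <- vapply(result$lines, function(l) abs(line_u_at_v(l, vmid) - target_u),
                 numeric(1))
    best <- result$lines[[which.min(du)]]
    dev <- angle_between(best, r$standard)
    devs[[length(devs) + 1]] <- data.frame(row_id = r$id, theta = dev$theta,
                                           abs_theta = dev$abs_theta)
  }
  loc_err <- localization_error(result$localization$world_point,
                                scene$truth$headland$world)
  list(deviations = do.call(rbind, devs), loc_error = loc_err,
       beta_deg = result$beta_deg, result = result)
}

#' Evaluate a set of scenes
#'
#' @param scenes List of `field_scene` objects (e.g. from
#'   [make_fixture_suite()]).
#' @param config Pipeline configuration.
#' @return A list with `deviations` (data.frame with `scene`, `row_id`,
#'   `theta`, `abs_theta`), `summary` (a [summarize_deviations()] result),
#'   `loc_errors` (numeric vector of Euclidean errors, m).
#' @export
evaluate_scene_set <- function(scenes, config = default_config()) {
  all_dev <- list(); loc <- numeric(length(scenes))
  for (i in seq_along(scenes)) {
    ev <- evaluate_scene(scenes[[i]], config)
    d <- ev$deviations; d$scene <- i
    all_dev[[i]] <- d
    loc[i] <- ev$loc_error$euclidean
  }
  deviations <- do.call(rbind, all_dev)
  list(deviations = deviations,
       summary = summarize_deviations(deviations$theta),
       loc_errors = loc)
}

#' Localization error table from true/measured coordinate pairs
#'
#' Computes per-axis, Euclidean and relative errors for each pair, in the
#' layout of a standard stereo-localization evaluation table.
#'
#' @param pairs data.frame with columns `true_x, true_y, true_z, meas_x,
#'   meas_y, meas_z` (a CSV path is also accepted).
#' @return The input with columns `dX`, `dY`, `dZ`, `euclidean`,
#'   `relative_pct` appended.
#' @export
evaluate_localization_table <- function(pairs) {
  if (is.character(pairs)) pairs <- utils::read.csv(pairs)
  need <- c("true_x", "true_y", "true_z", "meas_x", "meas_y", "meas_z")
  stopifnot(all(need %in% names(pairs)))
  out <- pairs
  out$dX <- out$dY <- out$dZ <- out$euclidean <- out$relative_pct <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    e <- localization_error(unlist(pairs[i, c("meas_x", "meas_y", "meas_z")]),
                            unlist(pairs[i, c("true_x", "true_y", "true_z")]))
    out$dX[i] <- e$dX; out$dY[i] <- e$dY; out$dZ[i] <- e$dZ
    out$euclidean[i] <- e$euclidean; out$relative_pct[i] <- e$relative
  }
  out
}
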