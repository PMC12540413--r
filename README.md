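# headturn

Vision-based headland-turn planning and visualization for ridge-planted row
crops (soybean at the V3–V8 stage is the motivating case). When a
camera-guided machine reaches the end of its pass it must localize the
headland — the bare turning strip where the rows stop — measure how the crop
rows run, and steer a feasible arc onto the next pass. `headturn` implements
that pipeline for R:

* **Row segmentation** — HSV thresholding of canopy green followed by a
  staged morphological opening (erosion kernels (6−i, 6−i), dilation kernels
  (i, i) for i ∈ {1, 3, 5}) and area-filtered contour extraction.
* **Centerline features** — full-width horizontal ROI strips (40 px tall,
  60 px apart) are intersected with each row contour; intersection centroids
  become per-row feature points after area screening.
* **Centerline fitting** — orthogonal (total) least squares per contour;
  orientation β reported in (−90°, 90°] against the horizontal image axis;
  signed angular deviation θ against a reference line, with mean / MAE /
  max summaries.
* **Stereo localization** — depth from disparity (Z = f·B/d), bounding-box
  reduction by center pixel + median core disparity, camera→world transform
  P_W = R_X⁻¹(γ)·P_C + T, and error metrics (per-axis, Euclidean, relative).
* **Arc planning** — R = min(|X_W|, |Z_W|) subject to R > R_min; center from
  the printed case split; swept angle α = β (β > 0) or 180° + β (β < 0);
  waypoints smoothed by a natural cubic spline on chord length.
* **Path visualization** — world→camera→pixel projection with a 5-coefficient
  radial–tangential distortion model, boundary clamping with counts, and
  disc-marker overlay rendering.
* **Synthetic scenes** — a seeded generator reproducing the planting geometry
  (ridge base 1.100 m, platform 0.700 m, three rows at ±0.225 m and the
  centerline, camera 2 m up, pitched 30°) with straw/shadow/missing-plant
  clutter and *exact* ground truth: crop mask, per-row standard lines, dense
  depth, headland box and world position.

See `vignettes/headland-turn-methods.Rmd` for the model, parameter and
design discussion.

## Worked example

```r
library(headturn)

# a synthetic field scene with known truth: rows at 80 deg azimuth
sc <- render_scene(scene_config(row_azimuth_deg = 80, seed = 42))
sc
#> field_scene: 640x480, azimuth 80.0 deg, seed 42
#>   headland bbox (294, 260, 393, 304), target (0.293, 0.000, 4.491) m

res <- run_pipeline(sc$image, sc$disparity,
                    list(detection(sc$truth$headland$bbox)),
                    camera_pose_override = sc$camera$pose)

res$localization
#> localization3d: pixel (344, 282), depth 4.889 m
#>   camera (0.293, 0.513, 4.889)  world (0.293, 0.000, 4.491)
res$plan
#> arc_spec: R=2.493 m, O=(2.493, 0.000, 1.997), alpha=79.625 deg, left turn
#> planned_path: 158 waypoints, chord length 5.463 m, terminal offset 0.451 m
sapply(res$lines, line_angle)
#> 69.13 74.53 79.63 80.50   # per-contour orientations, degrees

angle_between(res$lines[[2]], sc$truth$rows[[2]]$standard)$theta
#> 0.523                     # signed deviation from the row's standard line
```

Reading the numbers: the headland box center lifts to (0.293, 0, 4.491) m in
the world frame — 4.5 m ahead, slightly left. The rows were rendered at 80°;
the fitted centerlines recover orientations near 80° (the extra ~69°/75°
lines come from clutter-fragmented row pieces), and the chosen central row
deviates 0.5° from its ground-truth standard line. The planner turns left
with a 2.49 m radius over 79.6°; `res$overlay` holds the image with the
projected path drawn on it.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/headturn.R simulate --n 20 --seed 7 --out scenes/
Rscript inst/cli/headturn.R run --image scenes/scene_002/image.png \
    --disparity scenes/scene_002/disparity.tsv --config cam.yaml --out out/
Rscript inst/cli/headturn.R evaluate --scenes scenes/ --out report/
```

`run` writes `feature_points.csv`, `arc_spec.json`, `waypoints.csv`,
`projection.json` and `overlay.png`. Configuration is a strict YAML schema
over `default_config()` (unknown keys are rejected); for scenes produced by
the bundled generator, set `camera: {gamma_deg: -30}` — the ground-viewing
pose (see the vignette's frame-convention discussion).

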