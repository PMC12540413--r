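---
title: "Methods: headland-turn planning and visualization for ridge-planted row crops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: headland-turn planning and visualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headturn)
```

## The problem

A camera-guided agricultural vehicle working ridge-planted soybean must turn
at the headland — the unplanted strip where the crop rows end. Doing that
well takes three pieces of perception and one of planning:

1. **Where is the headland?** A detector supplies a bounding box in the
   image; stereo disparity lifts it to a 3D position.
2. **Which way do the rows run?** The crop rows are segmented, each row is
   summarized by a straight centerline, and the centerline's orientation
   relative to the image axis gives the row azimuth.
3. **What turn to make?** The headland position and row azimuth fix a
   circular arc in the world frame (radius, center, swept angle), smoothed
   with a cubic spline.
4. **Show it.** The planned path is projected back into the image for
   operator display and downstream tracking.

`headturn` implements all four stages plus a seeded synthetic scene
generator with exact ground truth, so every stage is testable without field
imagery.

## Coordinate frames and the pitch-sign choice

The world frame has $Z_W$ forward, $Y_W$ up, and $X_W$ lateral (positive to
the left of the $Z_W$ axis). The camera sits at $T = (0, 2, 0)$ m and is
related to the world frame by a rotation $R_X(\gamma)$ about $X_W$:

$$P_W = R_X^{-1}(\gamma)\,P_C + T, \qquad P_C = R_X(\gamma)\,(P_W - T).$$

For $\gamma = 30^\circ$ the component forms are

$$X_W = X_C,\quad
Y_W = \tfrac{\sqrt3}{2} Y_C + \tfrac12 Z_C + 2,\quad
Z_W = -\tfrac12 Y_C + \tfrac{\sqrt3}{2} Z_C,$$

which `camera_to_world()` and `world_to_camera()` reproduce exactly (they
are tested as an inverse pair to $10^{-9}$ on random points).

One genuine ambiguity had to be resolved: under this sign convention a
camera with $\gamma = +30^\circ$ has its optical axis *rising* with
distance, so the ground plane is essentially invisible to it — yet the
physical rig is described as looking down at the field. We keep the
transform equations exactly as written (so all closed-form checks at
$\gamma = 30^\circ$ hold), and have the synthetic scene generator build its
pose with `gamma = -camera_pitch`, which points the optical axis at the
ground *through the very same functions*. The system is therefore
self-consistent: rendering, truth projection, localization and path
display all share one convention. A side effect is that image rows grow
with distance (far ground appears lower in the frame); nothing downstream
depends on that orientation.

Pixels use a top-left origin, $u$ rightward, $v$ downward, with pixel
centers at integer coordinates; coordinates are continuous everywhere and
rounded only when drawing. Angles are degrees at every API boundary and
radians internally.

Projection is the standard pinhole model $u = f_x X_C / Z_C + c_x$,
$v = f_y Y_C / Z_C + c_y$, preceded by a five-coefficient radial–tangential
distortion model $(k_1, k_2, k_3, p_1, p_2)$ applied to normalized
coordinates. The all-zero model (the default) is the identity; the forward
model is applied analytically inside projection rather than as a post-hoc
remap. Points behind the camera are an error for single-point projection
and are dropped (and counted) in path projection; projected points outside
the frame are clamped to the border and counted, never silently discarded.

## Stereo localization

Depth follows triangulation, $Z_C = f B / d$, with focal length $f$ in
pixels and baseline $B$ in meters (defaults 400 px and 0.075 m, typical of
a compact stereo module). Disparities $\le 0$ are invalid. A detection box
is reduced to one 3D point as follows: the representative pixel is the box
center, and the depth comes from the median of valid disparities in a core
window extending `floor(w/4)` columns and `floor(h/4)` rows to each side of
that pixel. The window is deliberately symmetric about the center pixel:
for a ground-plane scene, disparity varies only with the image row, so the
median of an odd, symmetric window equals the center-pixel value exactly,
and exact-disparity localization recovers the ground truth to floating
point (the test bound is $10^{-6}$ m). The median makes the reduction
robust when the box edges straddle background.

Localization accuracy is reported as per-axis absolute errors, their
Euclidean norm, and the relative error (Euclidean error over the norm of
the true position, in percent). All statistics are computed in full
precision and rounded only for display: the bundled evaluation table mixes
rounded and unrounded reporting in its source, and recomputing at full
precision is the only self-consistent choice.

## Row segmentation

Crop pixels are selected in HSV space: a pixel is kept iff hue, saturation
and value all fall inside a box. The defaults, $H \in [70^\circ,
170^\circ]$, $S \in [0.25, 1]$, $V \in [0.20, 1]$, bracket healthy canopy
green while excluding soil (hue near 25°), straw (near 48°), sky, and
moderate shadow; all six bounds are configurable because real thresholds
are camera- and crop-dependent.

The mask is then cleaned by a staged morphological opening: for each index
$i$ in the schedule, an erosion with a $(6-i)\times(6-i)$ rectangular
element followed by a dilation with an $(i)\times(i)$ element. The default
schedule is $i \in \{1, 3, 5\}$ — exactly three openings whose erosion
kernels shrink $(5, 3, 1)$ while the dilation kernels grow $(1, 3, 5)$:
early passes remove speckle, the final pass reconnects fragmented row
segments (a $5\times5$ dilation bridges gaps up to 4 px). The index set
stops at 5 because $i = 7$ would demand a degenerate $(-1)\times(-1)$
erosion kernel. Structuring elements are filled rectangles and pixels
outside the image are treated as background; since the underlying
morphology library replicates borders instead, the package zero-pads
before each operation and crops after.

Contours are the connected components of the hole-filled mask, each
carried with its filled region (the downstream intersection needs areas,
not outlines), filtered by a minimum area of 500 px² at 640×480 and scaled
by image area otherwise.

## Feature points and centerline fitting

Full-width horizontal ROI strips of height 40 px are laid from the top of
the image at 60-px intervals (strips that would overrun the bottom edge
are dropped). Each strip is intersected with each filled contour by a
pixelwise AND; the intersection is split into connected components, so a
fractured row contributes separate regions rather than one smeared one.
Regions below 50 px² are screened out — small intersections are exactly the
ones whose centroids wander under holes and fractures. Each surviving
region contributes its binary centroid
$C_x = \sum x / N$, $C_y = \sum y / N$ at sub-pixel precision, grouped by
contour for per-row fitting.

Each contour's centroids are fitted with a straight line by orthogonal
(total) least squares: the line passes through the centroid of the points
along the principal axis of their scatter, minimizing perpendicular
distance. (The printed form of the objective in our source repeats $v_y$
in both residual terms, which makes it degenerate; perpendicular-distance
least squares is the standard reading and is what a principal-axis
decomposition solves.) The direction is canonicalized to $v_y \ge 0$ and
orientations are undirected, reported in $(-90^\circ, 90^\circ]$ relative
to the horizontal image axis.

Accuracy against a reference is measured as the signed angle between the
fitted line and a *standard line* (in evaluation, the segment joining the
midpoints of a row's near and far edges). The magnitude equals the
classic slope formula $\theta = \arctan|{(m_2 - m_1)}/{(1 + m_1 m_2)}|$,
but we compute it from the wrapped orientation difference so perpendicular
pairs ($m_1 m_2 = -1$) and vertical lines need no special case. In image
coordinates, negative $\theta$ means the fitted line leans left of the
standard line. Summaries report the signed mean (systematic bias), the
mean absolute error, and the maximum absolute deviation.

## Arc planning

Given the headland's ground-plane position $(X_W, Z_W)$ and the row
azimuth $\beta$:

* **Radius** $R = \min(|X_W|, |Z_W|)$, required to exceed the vehicle's
  minimum turning radius $R_\min$ (default 1.5 m); otherwise the turn is
  infeasible and the planner says so rather than guessing.
* **Center**: if $R = |X_W| < |Z_W|$, $O = (\mathrm{sign}(X_W) R,\, 0,\,
  Z_W - R)$; otherwise $O = (\mathrm{sign}(X_W) R, 0, 0)$.
* **Swept angle**: $\alpha = \beta$ for $\beta > 0$ and $\alpha = 180^\circ +
  \beta$ for $\beta < 0$; the two branches partition the half turn
  ($\alpha(\beta) + \alpha(-\beta) = 180^\circ$). $\beta = 0$ is rejected as
  degenerate.

The arc is parameterized $P(t) = O + R(-\mathrm{sign}(X_W)\cos t,\, 0,\,
\sin t)$, $t \in [0, \alpha]$, which anchors the start point on the
vehicle's forward axis — for the $|X_W| < |Z_W|$ case with $\alpha =
90^\circ$ the terminal point lands exactly on the target. The traversal
anchor is our choice (the source geometry implies but does not state it),
and a straight lead-in from the vehicle origin to the arc start is
prepended when they differ. For $|Z_W| \le |X_W|$ the printed center rule
cannot terminate on the target for general $\alpha$; the path is emitted
as specified and the terminal-to-target distance is reported as a
diagnostic rather than silently absorbed.

The combined waypoints are re-smoothed with natural cubic splines in $X$
and $Z$ parameterized by cumulative chord length — boundary conditions and
parameterization are our choices; natural ends avoid inventing end
curvature, and chord length is the standard parameterization for nearly
uniform samples. The spline solver is written in the package (Thomas
algorithm on the interior second-derivative system) because the planner's
contract exposes per-segment coefficients, which `stats::splinefun()` does
not; `stats` instead serves as the independent oracle in the tests.
Defaults: 100 arc samples, lead-in sampled at the same spacing.

One practical wrinkle: with a forward-facing camera the detected headland
is nearly straight ahead ($|X_W| \approx 0$), which the radius rule
correctly rejects as un-turnable. The pipeline therefore plans toward the
*adjacent working pass*: the planner input is the headland position offset
laterally by `turn_offset_x` (default 2.2 m, about two ridge spacings —
skip-row turning). The offset is configuration; the planner itself is
unchanged.

## The synthetic scene generator

The generator emulates the planting geometry the pipeline targets: a ridge
with base width 1.100 m, platform 0.700 m, height 0.250 m, three rows on
the platform at the centerline and ±0.225 m, camera 2 m above ground
pitched 30° at the field, 640×480 intrinsics with $f_x = f_y = 400$ px,
stereo $f = 400$ px, $B = 0.075$ m. Rows run at a configurable azimuth
(suite default spans 60°–120°) and terminate at a bare headland band.

Plants are overlapping green ellipses on the ground plane with per-pixel
hue jitter inside the segmentation's green range; the in-row canopy
half-length equals the plant spacing so neighbouring canopies overlap —
soybean rows close within-row early, and a single missing plant should
thin a row, not sever it. Clutter comes in three forms, each colored or
shaped to challenge a specific stage: straw streaks (beige, outside the
green hue range), a diagonal brightness gradient standing in for shadow
(scales RGB, hence value, leaving hue and saturation fixed), and random
per-plant dropout. Presets: low (2 streaks, 0.10 shadow, 2% dropout),
medium (8, 0.30, 8%), high (15, 0.45, 20%).

Depth is the exact ray–ground intersection under the package's own camera
conventions and disparity is exactly $fB/Z_C$, so localization tests are
limited only by floating point. Ground truth records the per-pixel crop
mask, each row's standard line (projected row-axis endpoints) with its
image orientation, the headland bounding box, and the headland's world
position computed analytically from the box-center ray — independently of
the disparity map, so exact-disparity recovery is a genuine end-to-end
check of the chain, not a tautology.

Deliberate simplifications, and what they mean for test evidence: plant
height is ignored (canopies are painted on the ground plane), the ridge
cross-section does not displace depth, shadow is a global gradient rather
than cast geometry, and the stereo matcher's failure modes (speckle,
occlusion fringes) are not simulated. Passing tests therefore demonstrate
the geometry, the fitting and the planning under controlled clutter — they
do not certify segmentation thresholds against real field radiometry, nor
localization against real matcher noise.

Determinism: a scene is a pure function of (config, seed); the generator
runs under an isolated RNG scope, and identical inputs give bit-identical
images, disparity and truth.

## Numerical choices and degenerate inputs

* Orientation wrap-around: all line comparisons are modulo 180° into
  $(-90°, 90°]$, so an 80° vs −80° pair deviates by 20°, not 160°.
* Near-vertical lines: endpoints at $x = 0$ and $x = W$ are refused when
  $|v_x| < 10^{-6}$; callers fall back to top/bottom-edge intersections.
* Invalid disparity (≤ 0), points behind the camera, empty regions,
  all-coincident fit points, zero azimuth and sub-minimum turn radii all
  raise typed errors rather than propagating NaNs; the pipeline labels the
  failing stage.
* Problem sizes used by the shipped tests: 640×480 scenes, a 20-scene
  stratified suite for parameter recovery, 1000-point transform round
  trips, 100-point distortion oracle comparisons, and 10 random spline
  systems — sizes chosen to exercise the code paths well while keeping a
  full test run around a minute of compute.

## Known limitations

* The heuristic headland proposal (`detect_headland_heuristic()`) is a
  deliberately simple mask-termination rule for weights-free operation; it
  assumes rows recede toward increasing image row under the package's
  conventions and is no substitute for a trained detector.
* Fitting is per contour: when clutter severs a row, each fragment is
  fitted (or skipped if it spans fewer than two strips); there is no
  cross-fragment merging or temporal tracking.
* The planner is purely geometric — no vehicle kinematics, clothoids, or
  obstacle handling; $\alpha$ depends on the azimuth alone and is not
  clipped against target overshoot.
* Segmentation defaults are tuned to the synthetic radiometry; real
  deployments must calibrate the HSV box and the stereo parameters to
  their camera.
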