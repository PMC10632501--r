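---
title: "Procedural synthetic training data for animal detection, tracking and pose estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Procedural synthetic training data for animal detection, tracking and pose estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthrig)
```

## Why synthesize training data

Deep networks for animal detection, multi-animal tracking, pose estimation
and segmentation need large annotated image sets, and hand annotation is the
bottleneck — especially at the pixel level or for dozens of keypoints per
individual. `synthrig` takes the opposite route: given a low-polygon
articulated 3D model of the study animal, it *renders* annotated images. The
annotations — bounding boxes, per-keypoint 2D/3D coordinates, occlusion
flags, instance masks — come for free and are exact, because the generator
knows the scene it drew.

The images are deliberately not photorealistic. The pipeline relies on
*domain randomization*: terrain shape, scattered clutter, subject pose and
appearance, lighting, camera intrinsics and post-processing are all
over-varied so aggressively that real footage falls inside the training
distribution. What matters is that every source of variation is randomized,
reproducible from a single seed, and annotated consistently.

## The randomization hierarchy

Scene construction is layered from computationally most to least expensive,
each level with its own update period (defaults 20 / 5 / 1 / 1 iterations):

1. **Terrain.** A square ground plane is displaced by the red channel of a
   procedurally generated RGB control map: multi-octave value noise, with
   0.5 the mean ground height, 1.0 a `+amplitude` and 0.0 a `-amplitude`
   shift. The green channel blends a two-color procedural ground material;
   the blue channel is reserved for user extensions and does not affect the
   default pipeline.
2. **Assets.** Scatterers draw one mesh per iteration from their
   (normalized, untextured) asset set and place a uniformly drawn number of
   instances at random positions, sizes and yaws, resting each instance's
   bounding-box bottom on the heightfield. All instances of one scatterer
   share one noise-blended two-color material. A built-in primitive library
   (boxes, slabs, cylinders, icospheres, pebbles) is the default asset set.
3. **Subjects.** Instances from the digital population are placed and posed
   (next section).
4. **Lighting, camera, post-processing.** Re-randomized every iteration:
   a directional light, 0–3 colored spotlights, ambient level, exponential
   distance fog toward a random sky color; a pinhole camera aimed at a
   random subject; color temperature/tint, saturation, contrast, vignette
   and Gaussian grain on the render pass only.

Regenerating a lower level forces regeneration of everything above it —
assets cannot outlive the terrain they rest on. Every randomized element
draws from its own seed, derived by hashing `(master seed, element tag,
iteration)`, so a run is bitwise reproducible and adding a new element never
perturbs existing streams. The subject stream hangs off a separate
`subject_seed`, so the same environments can be repopulated with different
animals by changing one number.

## Subjects: population, placement, posing

A subject model is a triangle mesh rigidly bound to an armature: every
vertex belongs to exactly one bone, bones form a tree, each bone's joint
carries per-axis angle limits and one of three groups — `mesh_interacting`
(legs, posed against the environment), `mesh_independent` (head, antennae —
randomized freely within limits), or `fixed`. Rigid per-bone binding is an
appropriate simplification for arthropods, whose exoskeleton barely deforms;
it also makes forward kinematics exactly distance-preserving within a bone,
which the tests assert to 1e-9.

`build_population()` expands the model list into a population: class counts
follow the configured fractions with largest-remainder rounding (fractions
0.2/0.6/0.2 at size 100 give exactly 20/60/20); each instance draws a scale
from `[1 - v, 1 + v]` (uniform — the least-informative choice for a quoted
"percent variation" — clipped below at 0.05) and hue/brightness/contrast/
saturation modifiers from the configured ranges. Default appearance ranges
(hue ±15°, brightness ±0.1, contrast and saturation 0.8–1.2) are this
package's own defaults and fully configurable. Each instance also receives a
unique ID color via the bijection `k -> (k, k/256, k/65536) mod 256`, which
never produces the reserved background black.

**Placement** rejection-samples a position above the terrain and a random
center rotation (yaw free, pitch/roll bounded by `tilt_range`), rejecting
candidates that start below ground or whose collision proxies intersect
anything, then translates the subject along its down-vector (world −Z
rotated by the center rotation) to first proxy contact. If the trace leaves
the world, a new rotation is drawn. A retry cap (default 100) bounds the
loop; the original procedure retries unboundedly.

**Collision proxies** are sphere chains: each bone's segment vertices are
sliced along the bone's principal axis into up to six spheres fitted to the
perpendicular spread. A single sphere per bone — the simpler alternative —
has radius of order half the body length on elongated bones, which made
dropped subjects rest on that ball and hover so high that no foot could
reach the ground; the sphere chain behaves like the capsule proxies game
engines use and keeps resting heights honest at a few percent of body size.

**Posing** proceeds per leg chain: a downward ray from a jittered point
above the foot's rest position finds the first surface (terrain, asset, or
another subject's proxy); cyclic coordinate descent (CCD) with per-axis
clamping to the joint limits then solves the chain to that target. CCD was
chosen over a simultaneous full-body solver because the procedure is
naturally per-leg and CCD's per-joint updates make the joint-limit handling
exact; its known weakness — slow creep near full extension — is handled by a
plateau cut-off (a sweep that improves the tip distance by less than 1% of
the tolerance ends the solve). A leg is `grounded` when the tip lands within
`ik_tolerance` of the target (default 5e-3 world units, about 0.25% of the
built-in subject's body length; 100 sweeps maximum). Legs drawn for
deliberate mid-air posing (default fraction 0.15), or legs whose ray finds
nothing, are solved toward a uniform point inside the chain's reach ball
with a single restricted sweep, mirroring the original's
restricted-iteration trick; the restricted count (1) and the mid-air
fraction are package choices, config-exposed, since the original publishes
neither. Mesh-independent joints draw each axis uniformly within its limits.

## Rendering and image passes

Rendering is a deterministic software z-buffer rasterizer — the pipeline
needs controllable, reproducible geometry buffers, not photorealism, so a
game engine would add fidelity but no structure. Conventions: right-handed
world, Z up; camera +Z forward, +X right, +Y down; pixels 0-based from the
top-left with centers at integer + 0.5; principal point at the image center;
`fx = focal_length * width / sensor_width`. Depth and vertex attributes are
interpolated perspective-correctly; triangles crossing the near plane
(0.05 units) are dropped rather than clipped, which is invisible at the
camera distances the generator draws.

Four co-registered passes are produced per scene:

* **render** — Lambertian shading (ambient + directional + cone-falloff
  spotlights), exponential fog toward the sky color (`exp(-density * depth)`
  of the surface survives), exposure as a `2^EV` gain, then the
  post-processing stack. Shadows and global illumination are deliberately
  omitted; this is a documented fidelity gap, not a pipeline gap.
* **id** — every subject pixel carries its instance's unique RGB id color;
  terrain, assets and background are exactly (0,0,0). This pass is the
  source of occlusion flags, occupancy, masks and label maps.
* **depth** — camera-plane distance in world units. On disk it is stored as
  16-bit fixed point packed into the R (high byte) and G (low byte)
  channels of an 8-bit RGB PNG, with the linear near/far mapping recorded
  in the sample file; `decode_depth()` reverses it. (A native 16-bit gray
  PNG would be equivalent; the packed form is this package's on-disk
  dialect.)
* **normal** — per-face unit normals, world- or view-space, encoded
  `(n + 1) / 2`.

Only the render pass is post-processed; id/depth/normal stay exact.

## Annotations

Per sample the generator stores camera position/rotation, diagonal field of
view, the full 4×4 view-projection matrix, intrinsics and the depth
near/far; per subject the bounding box, occupancy, and per-keypoint 2D
pixel, camera-relative 3D position and a visibility flag. Bounding boxes are
the min/max rectangle over *all* projected keypoints, occluded ones
included, clipped to the image — the same hull definition the evaluation
uses. A keypoint is `visible` when some pixel of its 3×3 neighborhood
carries the subject's id color at a depth within 1% of the keypoint's own;
the neighborhood and tolerance absorb rasterization aliasing around
one-pixel-wide appendages. Occupancy is the fraction of box pixels carrying
the id color. Numbers are serialized at 17 significant digits, so
write/read round trips are exact; all of this is asserted in the test suite,
including the invariant that stored 2D keypoints equal the stored 3D points
pushed through the stored matrices to less than 1e-9 px.

Exporters translate a dataset losslessly into YOLO labels (6-decimal
normalized boxes, recoverable within 0.5 px), COCO JSON (visibility codes
2/1/0 for visible/occluded/out-of-frame — a convention this package fixes,
since only the exclusion toggle is inherited; uncompressed column-major RLE
or marching-squares polygons with ≤1 px simplification), wide keypoint
tables (likelihood fixed at 1.0 — synthetic ground truth has no annotation
uncertainty), 8-bit segmentation label maps (binary or per-class), and a 3D
pose format carrying the full camera geometry. All exporters are read-only
over the dataset.

## Tracking

The tracker is detection-based buffer-and-recover: per frame, detections are
filtered (confidence ≥ 0.5, smaller box side ≥ 20 px — boundary inclusive),
deduplicated by greedy NMS at IoU 0.45, associated to the constant-velocity
Kalman predictions of live tracks by the Hungarian method on Euclidean
center distances gated at 100 px, and matched tracks updated (Joseph-form
covariance update, so the covariance stays symmetric PSD). Unmatched tracks
coast on their prediction — and keep reporting that predicted position, so
short detection gaps do not fragment tracks — for up to 30 frames before
termination; unmatched detections spawn tracks with strictly increasing,
never-reused ids. Gate, buffer and the noise scales (process 1e-2 on
velocity, measurement 1.0) are package defaults, config-exposed: the
original states only that default settings were used. Center-distance cost
matches the center-based evaluation; IoU cost is available as an option.
The tracker contains no randomness at all.

## Evaluation statistics

* **AP** over 13 confidence thresholds equally spaced on [0.2, 0.8]. A
  detection is correct when its center lies within 5% of the image width of
  an unmatched ground-truth center (greedy nearest matching, descending
  confidence — the matching rule is this package's documented choice and is
  verified against brute-force enumeration). With descending thresholds,
  `AP = Σ (R_n − R_{n−1}) P_n`, seeded with `R_0 = 0`; at the maximal
  threshold no detections are returned, so precision there is unity by
  definition. This is the weighted-mean form, not trapezoidal
  interpolation. **mAP** is the arithmetic mean of per-case APs.
* **MOTA** `= 1 − (FN + FP + IDS) / Σ gt`. Per frame, gt and inferred
  tracks are matched by the Hungarian method gated at `d_max` (50 px at 4k,
  i.e. 2% of frame width at other resolutions; optimal rather than greedy
  matching is this package's documented resolution of an unstated detail).
  An identity switch is counted when a gt id's matched inferred id differs
  from its stored correspondence, after which the new identity is treated
  as correct. During overlap events — maximal consecutive frame runs where
  any two gt tracks are closer than `d_max` — correspondence changes are
  neither counted nor stored, so transient swaps between crossing animals
  are suppressed, while FN/FP are still counted.
* **Pose error**: mean pixel distance over keypoints with confidence ≥ 0.6
  (the common pose-estimation default), divided by the body length `l` in
  pixels, × 100. An empty retained set raises an explicit undefined-result
  error rather than returning 0. The retained fraction is reported
  alongside, since a network keeping ≤50% of its keypoints is itself a
  finding.
* **ACR** (average class-wise recall): per class and image
  `(ŷ − (FP + FN)) / ŷ`, averaged over images, then classes, × 100. The
  printed double-sum form of this statistic lacks the inner 1/n; the prose
  calls it an average, and this package normalizes explicitly — for a
  single image both readings coincide, which is where the exact test values
  (85.0 for ŷ=200, FN=20, FP=10) live.

Two seeded simulators (`simulate_tracks()`, `simulate_detections()`) stand
in for a trained detector in tests: constant-velocity targets with optional
crossings, Bernoulli dropout, Gaussian center jitter and Poisson clutter.
They emulate detector *output statistics*, not images — so the end-to-end
tracker tests demonstrate the tracking and scoring machinery, not detection
robustness on real footage.

## What the tests do and do not show

The suite verifies the machinery exactly: FK/IK geometry against closed
forms, the rasterizer against per-pixel half-space coverage, annotations
against reprojection identities, every metric against brute-force oracles,
bitwise reproducibility of full runs, and export round trips. Problem sizes
are kept small by design — 128×128 passes, terrain tessellation 48, 3–4
subjects, 200 tracked frames — since every property checked is
size-independent. What the tests cannot show is transfer: whether a network
trained on these images performs on real recordings depends on model
fidelity and rendering realism (no shadows, no global illumination, no
photo textures), and must be established per application with trained
networks and real benchmark footage, which is outside this package's scope.

## Known limitations

* Lambertian shading without shadows or HDRI lighting; solid/fog sky only.
* Near-plane clipping drops, rather than clips, crossing triangles.
* Proxy-based collision (sphere chains, asset AABBs) admits small
  interpenetrations that triangle-exact collision would reject.
* Per-leg sequential IK cannot coordinate whole-body posture shifts.
* The COCO `iscrowd`/RLE dialect covers uncompressed RLE only.
* Mesh preparation (cleanup, retopology, texture baking) is out of scope;
  models arrive as OBJ + armature sidecar.
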