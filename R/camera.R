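# Pinhole camera model, randomization and projection.
#
# Conventions: right-handed world with Z up; camera space has +Z forward,
# +X right, +Y down. Pixels are 0-based with the origin at the top-left and
# pixel centers at integer + 0.5; the principal point sits at the image
# center (W/2, H/2) in continuous pixel coordinates.

#' Construct a camera
#'
#' @param position length-3 world position.
#' @param rotation 3x3 world-to-camera is derived from this camera-to-world
#'   rotation matrix (columns = camera axes in world coordinates).
#' @param focal_length focal length (mm).
#' @param sensor_width,sensor_height sensor dimensions (mm).
#' @param resolution `c(W, H)` in pixels.
#' @param aperture f-number (depth-of-field proxy; large = sharp).
#' @param exposure EV offset applied as a `2^EV` gain at shading time.
#' @return a `synthrig_camera` with derived quantities (see
#'   [camera_derived()]).
#' @export
camera_model <- function(position, rotation, focal_length = 35,
                         sensor_width = 36, sensor_height = 24,
                         resolution = c(256, 256), aperture = 16, exposure = 0) {
  stopifnot(focal_length > 0, sensor_width > 0, sensor_height > 0,
            all(resolution > 0))
  cam <- list(position = as.numeric(position), rotation = rotation,
              focal_length = focal_length, sensor_width = sensor_width,
              sensor_height = sensor_height, resolution = as.integer(resolution),
              aperture = aperture, exposure = exposure)
  cam$derived <- camera_derived(cam)
  class(cam) <- "synthrig_camera"
  cam
}

#' Derived camera quantities
#'
#' Intrinsics in pixels (`fx = f * W / sensor_width`), the view matrix, the
#' 4x4 view-projection matrix mapping world homogeneous coordinates to
#' `(u * z, v * z, z, 1)` with `z` the camera-plane depth, and the diagonal
#' field of view `2 * atan(sensor_diag / (2 f))` in degrees.
#'
#' @param cam a camera list (see [camera_model()]).
#' @return list `fx`, `fy`, `cx`, `cy`, `K`, `view` (4x4), `view_projection`
#'   (4x4), `fov_diagonal_deg`.
#' @export
camera_derived <- function(cam) {
  W <- cam$resolution[1]; H <- cam$resolution[2]
  fx <- cam$focal_length * W / cam$sensor_width
  fy <- cam$focal_length * H / cam$sensor_height
  cx <- W / 2; cy <- H / 2
  Rwc <- t(cam$rotation)                       # world -> camera
  tvec <- -as.numeric(Rwc %*% cam$position)
  view <- rbind(cbind(Rwc, tvec), c(0, 0, 0, 1))
  K <- matrix(c(fx, 0, 0, 0, fy, 0, cx, cy, 1), 3, 3)
  P <- rbind(cbind(K %*% diag(3), c(0, 0, 0)), c(0, 0, 0, 1))
  diag_mm <- sqrt(cam$sensor_width^2 + cam$sensor_height^2)
  list(fx = fx, fy = fy, cx = cx, cy = cy, K = K, view = view,
       view_projection = P %*% view,
       fov_diagonal_deg = 2 * atan(diag_mm / (2 * cam$focal_length)) * 180 / pi)
}

# camera-to-world rotation looking from `eye` toward `at`, world Z up
look_at_rotation <- function(eye, at, up = c(0, 0, 1)) {
  fwd <- at - eye
  fwd <- fwd / vnorm(fwd)
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  if (vnorm(right) < 1e-9) right <- c(1, 0, 0) else right <- right / vnorm(right)
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  cbind(right, down, fwd)                       # columns: +X right, +Y down, +Z fwd
}

#' Spawn a randomized camera aimed at a subject
#'
#' The position is sampled in a spherical shell around a randomly chosen
#' subject; the boresight aims at the subject center and is then perturbed
#' by a random rotation of at most `offset_bound` degrees so the subject
#' does not always sit at the image center. Intrinsics are drawn from the
#' configured ranges.
#'
#' @param scene scene list with a non-empty `subjects`.
#' @param seed integer seed.
#' @param config list: `resolution`, `focal_range` (mm), `sensor` (c(w, h)
#'   mm), `distance_range` (world units), `elevation_range` (degrees above
#'   horizon), `offset_bound` (degrees), `exposure_range` (EV),
#'   `aperture_range`.
#' @return a `synthrig_camera`; the chosen subject index is attached as
#'   attribute `"subject"`.
#' @export
spawn_camera <- function(scene, seed, config = list()) {
  if (length(scene$subjects) == 0) stop("spawn_camera: scene has no subjects")
  cfg <- utils::modifyList(list(
    resolution = c(256, 256), focal_range = c(25, 60), sensor = c(36, 24),
    distance_range = c(4, 10), elevation_range = c(15, 75),
    offset_bound = 5, exposure_range = c(-0.3, 0.3),
    aperture_range = c(8, 16)), config)
  with_seed(seed, {
    si <- runif_int(c(1L, length(scene$subjects)))
    target <- scene$subjects[[si]]$center
    r <- runif1(cfg$distance_range)
    az <- stats::runif(1, 0, 2 * pi)
    el <- deg2rad(runif1(cfg$elevation_range))
    eye <- target + r * c(cos(az) * cos(el), sin(az) * cos(el), sin(el))
    R <- look_at_rotation(eye, target)
    if (cfg$offset_bound > 0) {
      ax <- stats::rnorm(3); ax <- ax / vnorm(ax)
      ang <- deg2rad(stats::runif(1, 0, cfg$offset_bound))
      R <- rot_about_axis(ax, ang) %*% R
    }
    cam <- camera_model(
      position = eye, rotation = R,
      focal_length = runif1(cfg$focal_range),
      sensor_width = cfg$sensor[1], sensor_height = cfg$sensor[2],
      resolution = cfg$resolution,
      aperture = runif1(cfg$aperture_range),
      exposure = runif1(cfg$exposure_range))
    attr(cam, "subject") <- si
    cam
  })
}

#' Project world points through a camera
#'
#' @param cam a `synthrig_camera`.
#' @param points n x 3 world points (or a length-3 vector).
#' @return data.frame `x`, `y` (continuous pixel coordinates), `depth`
#'   (camera-plane distance), `behind` (logical, `depth <= 0`).
#' @export
project <- function(cam, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  d <- cam$derived
  pc <- sweep(p, 2, cam$position, "-") %*% cam$rotation   # world -> camera
  z <- pc[, 3]
  behind <- z <= 0
  zs <- ifelse(behind, NA_real_, z)
  data.frame(x = d$cx + d$fx * pc[, 1] / zs,
             y = d$cy + d$fy * pc[, 2] / zs,
             depth = z, behind = behind)
}

# camera-space coordinates of world points
world_to_camera <- function(cam, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  sweep(p, 2, cam$position, "-") %*% cam$rotation
}
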