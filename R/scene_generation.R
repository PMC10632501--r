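# Procedural environment generation: value-noise control maps, terrain,
# asset scattering, lighting, and the randomization schedule.
#
# One environment per iteration is a pure function of (config, seed), built
# under a four-level hierarchy ordered from computationally most to least
# demanding: (1) terrain, (2) scattered assets, (3) subject placement and
# pose, (4) materials/lighting/camera/post-processing. Each level has its
# own update period; regenerating a lower level forces regeneration of all
# levels above it.

#' Multi-octave value noise on a grid
#'
#' Value noise: uniform lattice values interpolated with a smoothstep
#' kernel; octaves double the lattice frequency and halve the amplitude.
#'
#' @param resolution grid side length.
#' @param frequency base lattice frequency (cells across the grid).
#' @param octaves number of octaves.
#' @param seed integer seed.
#' @return resolution x resolution matrix, centered on 0, max abs <= 1.
#' @export
value_noise <- function(resolution, frequency = 4, octaves = 3, seed = 1) {
  out <- matrix(0, resolution, resolution)
  amp <- 1; norm <- 0
  for (o in seq_len(octaves)) {
    freq <- frequency * 2^(o - 1)
    lat <- with_seed(derive_seed(seed, "octave", o),
                     matrix(stats::runif((freq + 1)^2, -1, 1), freq + 1, freq + 1))
    u <- seq(0, 1, length.out = resolution) * freq
    i0 <- pmin(floor(u), freq - 1)
    f <- u - i0
    w <- f * f * (3 - 2 * f)            # smoothstep
    i0 <- i0 + 1L                        # 1-based
    # bilinear interpolation, vectorized over the grid
    a <- lat[i0, i0]; b <- lat[i0 + 1L, i0]
    c <- lat[i0, i0 + 1L]; d <- lat[i0 + 1L, i0 + 1L]
    wx <- matrix(w, resolution, resolution)
    wy <- matrix(w, resolution, resolution, byrow = TRUE)
    out <- out + amp * ((a * (1 - wx) + b * wx) * (1 - wy) +
                        (c * (1 - wx) + d * wx) * wy)
    norm <- norm + amp
    amp <- amp / 2
  }
  out / norm
}

#' Generate the RGB terrain control map
#'
#' The red channel encodes ground displacement around the mean height
#' (0.5 = mean), the green channel drives material blending, and the blue
#' channel is filled but unused by the default randomization routines.
#'
#' @param resolution map side length (>= 2).
#' @param noise_spec list with `octaves`, `frequency` and `amplitude`
#'   (relative, in `[0, 1]`; 0 gives a flat red channel at 0.5).
#' @param seed integer seed.
#' @return a `synthrig_rgb_map`: list of `red`, `green`, `blue` matrices in
#'   `[0, 1]`.
#' @export
generate_rgb_map <- function(resolution,
                             noise_spec = list(octaves = 3, frequency = 4, amplitude = 1),
                             seed = 1) {
  if (resolution < 2) stop("resolution must be >= 2")
  amp <- noise_spec$amplitude %||% 1
  red <- 0.5 + 0.5 * amp * value_noise(resolution, noise_spec$frequency,
                                       noise_spec$octaves, derive_seed(seed, "red"))
  green <- 0.5 + 0.5 * value_noise(resolution, noise_spec$frequency,
                                   noise_spec$octaves, derive_seed(seed, "green"))
  blue <- 0.5 + 0.5 * value_noise(resolution, noise_spec$frequency,
                                  noise_spec$octaves, derive_seed(seed, "blue"))
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  structure(list(red = clip01(red), green = clip01(green), blue = clip01(blue),
                 resolution = resolution),
            class = "synthrig_rgb_map")
}

#' Build a terrain heightfield from an RGB control map
#'
#' `height = (red - 0.5) * 2 * amplitude`: red 0.5 is mean ground height,
#' 1.0 is `+amplitude` and 0.0 is `-amplitude`. The green channel becomes
#' the material blend field.
#'
#' @param map a [generate_rgb_map()] result.
#' @param extent terrain side length (world units).
#' @param amplitude maximum absolute height (world units, >= 0).
#' @return a `synthrig_terrain`.
#' @export
build_terrain <- function(map, extent, amplitude) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(
    heightfield = (map$red - 0.5) * 2 * amplitude,
    material_field = map$green,
    extent = extent, amplitude = amplitude,
    resolution = map$resolution),
    class = "synthrig_terrain")
}

#' Terrain surface height at world (x, y)
#'
#' Bilinear interpolation of the heightfield; the terrain is centered on the
#' origin. Returns `NA` outside the extent.
#'
#' @param terrain a [build_terrain()] result.
#' @param x,y world coordinates (vectorized).
#' @return heights (world units).
#' @export
terrain_height <- function(terrain, x, y) {
  n <- terrain$resolution
  half <- terrain$extent / 2
  u <- (x + half) / terrain$extent * (n - 1)
  v <- (y + half) / terrain$extent * (n - 1)
  out <- rep(NA_real_, length(u))
  ok <- u >= 0 & u <= n - 1 & v >= 0 & v <= n - 1
  if (!any(ok)) return(out)
  u <- pmin(u[ok], n - 1 - 1e-12); v <- pmin(v[ok], n - 1 - 1e-12)
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  H <- terrain$heightfield
  idx <- function(i, j) H[cbind(i + 1L, j + 1L)]
  out[ok] <- idx(i0, j0) * (1 - fu) * (1 - fv) + idx(i0 + 1, j0) * fu * (1 - fv) +
    idx(i0, j0 + 1) * (1 - fu) * fv + idx(i0 + 1, j0 + 1) * fu * fv
  out
}

# terrain as a world-space triangle mesh with material-blended vertex colors
terrain_mesh <- function(terrain, material = NULL) {
  n <- terrain$resolution
  half <- terrain$extent / 2
  xs <- seq(-half, half, length.out = n)
  v <- cbind(rep(xs, times = n), rep(xs, each = n), as.numeric(terrain$heightfield))
  ii <- rep(seq_len(n - 1), times = n - 1)
  jj <- rep(seq_len(n - 1), each = n - 1)
  a <- (jj - 1L) * n + ii
  tris <- rbind(cbind(a, a + 1L, a + n + 1L),
                cbind(a, a + n + 1L, a + n))
  w <- as.numeric(terrain$material_field)
  if (is.null(material)) material <- list(color_a = c(0.35, 0.3, 0.25), color_b = c(0.6, 0.55, 0.45))
  cols <- outer(w, material$color_a) + outer(1 - w, material$color_b)
  mesh(v, tris, cols)
}

#' Define an asset scatterer
#'
#' @param assets named list of normalized asset meshes (largest extent 1).
#' @param size_range length-2 positive multiplier range.
#' @param count_range length-2 integer instance count range.
#' @param material optional `list(color_a, color_b)` two-color scheme; drawn
#'   randomly at scatter time when `NULL`.
#' @return a `synthrig_scatterer`.
#' @export
scatterer <- function(assets, size_range = c(0.5, 2), count_range = c(3, 10),
                      material = NULL) {
  if (length(assets) == 0) stop("scatterer asset_set must not be empty")
  if (size_range[1] <= 0 || size_range[1] > size_range[2]) stop("invalid size_range")
  if (count_range[1] <= 0 || count_range[1] > count_range[2]) stop("invalid count_range")
  structure(list(assets = assets, size_range = size_range,
                 count_range = as.integer(count_range), material = material),
            class = "synthrig_scatterer")
}

#' Scatter assets over a terrain
#'
#' Per scatterer: one asset mesh is drawn for the iteration, an instance
#' count is drawn uniformly from the count range, and each instance receives
#' a uniform size, a random yaw and a position on the terrain surface (the
#' instance's bounding-box bottom rests on the heightfield at its footprint
#' center). All instances of one scatterer share its material.
#'
#' @param scatterers list of [scatterer()].
#' @param terrain a [build_terrain()] result.
#' @param seed integer seed.
#' @return list of placed instances: `mesh` (world-space), `aabb`
#'   (`lo`, `hi`), `scatterer`, `asset_name`.
#' @export
scatter_assets <- function(scatterers, terrain, seed) {
  placed <- list()
  for (si in seq_along(scatterers)) {
    sc <- scatterers[[si]]
    with_seed(derive_seed(seed, "scatterer", si), {
      ai <- runif_int(c(1L, length(sc$assets)))
      asset <- sc$assets[[ai]]
      mat <- sc$material %||% list(
        color_a = stats::runif(3, 0.1, 0.9),
        color_b = stats::runif(3, 0.1, 0.9))
      count <- runif_int(sc$count_range)
      blend <- value_noise(8, 2, 1, derive_seed(seed, "scmat", si))
      for (k in seq_len(count)) {
        size <- runif1(sc$size_range)
        yaw <- stats::runif(1, 0, 360)
        half <- terrain$extent / 2 * 0.95
        x <- stats::runif(1, -half, half)
        y <- stats::runif(1, -half, half)
        R <- rot_axis(3, yaw)
        m <- asset
        # two-color noise-blended procedural material
        w <- (blend[(seq_len(nrow(m$vertices)) - 1L) %% 64 + 1L] + 1) / 2
        m$colors <- outer(w, mat$color_a) + outer(1 - w, mat$color_b)
        m <- mesh_transform(m, rotation = R, scale = size)
        zmin <- min(m$vertices[, 3])
        h <- terrain_height(terrain, x, y)
        m <- mesh_transform(m, translation = c(x, y, h - zmin))
        placed[[length(placed) + 1L]] <- list(
          mesh = m,
          aabb = list(lo = apply(m$vertices, 2, min), hi = apply(m$vertices, 2, max)),
          scatterer = si,
          asset_name = names(sc$assets)[ai] %||% as.character(ai))
      }
    })
  }
  placed
}

#' Randomization schedule state
#'
#' @param periods named integer vector/list with elements `terrain`,
#'   `assets`, `subjects`, `camera` (update period in iterations; the camera
#'   level must be 1 — it is re-randomized every iteration).
#' @return a `synthrig_schedule`.
#' @export
schedule_state <- function(periods = c(terrain = 20, assets = 5, subjects = 1, camera = 1)) {
  p <- unlist(periods)[c("terrain", "assets", "subjects", "camera")]
  if (any(is.na(p)) || any(p < 1)) stop("schedule periods must be >= 1")
  if (p[["camera"]] != 1) stop("camera level period must be 1")
  structure(list(periods = p), class = "synthrig_schedule")
}

#' Which hierarchy levels regenerate at an iteration
#'
#' Level k regenerates when `iteration %% period_k == 0`; regenerating a
#' lower (more expensive) level forces regeneration of all higher levels,
#' because terrain changes invalidate asset placement, which invalidates
#' subject placement, and so on.
#'
#' @param state a [schedule_state()].
#' @param iteration 0-based iteration index.
#' @return character vector of levels to regenerate.
#' @export
advance_schedule <- function(state, iteration) {
  levels <- c("terrain", "assets", "subjects", "camera")
  due <- iteration %% state$periods == 0
  first <- which(due)[1]
  if (is.na(first)) return(character(0))
  levels[seq(first, 4)]
}

#' Randomize the lighting rig
#'
#' @param config list with `spot_count_range`, `spot_intensity_range`,
#'   `directional_intensity_range`, `ambient_range`, `fog_range`,
#'   `color_ranges` (per-channel `[lo, hi]`), `extent` (spotlight placement
#'   radius), `height_range` (spotlight heights).
#' @param seed integer seed.
#' @return a `synthrig_light_rig`.
#' @export
randomize_lights <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    spot_count_range = c(0, 3), spot_intensity_range = c(0.2, 1),
    directional_intensity_range = c(0.4, 1), ambient_range = c(0.15, 0.4),
    fog_range = c(0, 0.02), color_ranges = list(c(0.6, 1), c(0.6, 1), c(0.6, 1)),
    extent = 20, height_range = c(5, 15), cone_range = c(20, 60)), config)
  with_seed(seed, {
    az <- stats::runif(1, 0, 2 * pi); el <- stats::runif(1, deg2rad(25), deg2rad(80))
    dir <- -c(cos(az) * cos(el), sin(az) * cos(el), sin(el))  # points down
    rc <- function() vapply(cfg$color_ranges, runif1, 0)
    n_spot <- runif_int(cfg$spot_count_range)
    spots <- lapply(seq_len(n_spot), function(i) {
      pos <- c(stats::runif(2, -cfg$extent / 2, cfg$extent / 2), runif1(cfg$height_range))
      aim <- c(stats::runif(2, -cfg$extent / 4, cfg$extent / 4), 0)
      d <- aim - pos
      list(position = pos, direction = d / vnorm(d),
           cone_deg = runif1(cfg$cone_range), color = rc(),
           intensity = runif1(cfg$spot_intensity_range))
    })
    structure(list(
      directional = list(direction = dir, color = rc(),
                         intensity = runif1(cfg$directional_intensity_range)),
      spotlights = spots,
      ambient = runif1(cfg$ambient_range),
      fog_density = runif1(cfg$fog_range),
      sky_color = c(runif1(c(0.4, 0.9)), runif1(c(0.4, 0.9)), runif1(c(0.5, 1)))),
      class = "synthrig_light_rig")
  })
}
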