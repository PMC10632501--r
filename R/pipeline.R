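# Orchestration: config validation/normalization, the scheduled generation
# loop, and single-iteration preview.
#
# Per-element seeds are pure functions of (master seed, element tag,
# iteration), so every scene is reproducible in isolation and adding a new
# randomized element never perturbs existing streams. The environment and
# subject streams use separate master seeds (subject_seed defaults to the
# environment seed + a tag), so identical environments can be populated
# with different subjects by changing only subject_seed.

default_config <- function() {
  list(
    general = list(n_samples = 10, resolution = c(256, 256),
                   output_dir = "synthrig_out", dataset_name = "dataset",
                   passes = c("render", "id", "depth", "normal"),
                   render_format = "png", jpg_quality = NULL,
                   normal_space = "world",
                   depth_near = 0.05, depth_far = 100),
    subjects = list(population = NULL, population_size = 10, per_scene = 3,
                    scale_variation = 0.33,
                    color_variation = list(hue = 15, brightness = 0.1,
                                           contrast = c(0.8, 1.2),
                                           saturation = c(0.8, 1.2)),
                    posing = list(ik_iterations = 100, restricted_iterations = 1,
                                  ik_tolerance = 5e-3, midair_fraction = 0.15,
                                  retry_cap = 100)),
    environment = list(
      terrain = list(resolution = 256, extent = 20, amplitude = 0.8,
                     noise = list(octaves = 3, frequency = 4, amplitude = 1)),
      scatterers = list(list(assets = "primitives", size_range = c(0.3, 1.5),
                             count_range = c(3, 8))),
      lights = list()),
    camera = list(resolution = NULL, focal_range = c(25, 60), sensor = c(36, 24),
                  distance_range = c(4, 10), elevation_range = c(15, 75),
                  offset_bound = 5, exposure_range = c(-0.3, 0.3),
                  aperture_range = c(8, 16)),
    post = list(temperature_range = c(-0.05, 0.05), tint_range = c(-0.03, 0.03),
                saturation_range = c(0.9, 1.1), contrast_range = c(0.95, 1.05),
                vignette_range = c(0, 0.3), grain_range = c(0, 0.02)),
    debug = list(seed = 1, subject_seed = NULL,
                 periods = c(terrain = 20, assets = 5, subjects = 1, camera = 1)))
}

#' Validate and normalize a generator configuration
#'
#' Fills defaults for omitted optional keys and returns either the
#' normalized config or stops with the list of problems.
#'
#' @param config a nested list (e.g. from [yaml::read_yaml()]), or a path to
#'   a YAML file.
#' @return the normalized config (class `synthrig_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(0)
  if (is.null(config$subjects)) errors <- c(errors, "missing 'subjects' block")
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  g <- cfg$general
  if (is.null(g$n_samples) || g$n_samples < 1) {
    errors <- c(errors, "general$n_samples must be >= 1")
  }
  if (length(g$resolution) == 1) cfg$general$resolution <- rep(g$resolution, 2)
  if (any(cfg$general$resolution < 32)) {
    errors <- c(errors, "general$resolution must be >= 32")
  }
  if (cfg$environment$terrain$amplitude < 0) {
    errors <- c(errors, "environment$terrain$amplitude must be >= 0")
  }
  if (cfg$environment$terrain$resolution < 2) {
    errors <- c(errors, "environment$terrain$resolution must be >= 2")
  }
  if (cfg$subjects$population_size < 1) {
    errors <- c(errors, "subjects$population_size must be >= 1")
  }
  if (length(errors) > 0) {
    stop("config validation error(s):\n  - ", paste(errors, collapse = "\n  - "))
  }
  if (is.null(cfg$debug$subject_seed)) {
    cfg$debug$subject_seed <- derive_seed(cfg$debug$seed, "subjects")
  }
  if (is.null(cfg$camera$resolution)) cfg$camera$resolution <- cfg$general$resolution
  cfg$debug$periods <- unlist(cfg$debug$periods)
  class(cfg) <- c("synthrig_config", "list")
  cfg
}

# resolve the population spec: entries may be built-in model names
# ("stick", "stick_antennae"), or list(mesh=, sidecar=) paths
resolve_population <- function(cfg) {
  entries <- cfg$subjects$population
  if (is.null(entries)) {
    entries <- list(stick = list(model = "stick", fraction = 1))
  }
  entries <- lapply(entries, function(e) {
    m <- e$model
    if (is.character(m)) {
      e$model <- switch(m,
        stick = make_stick_subject(),
        stick_antennae = make_stick_subject(antennae = TRUE),
        stop("unknown built-in model '", m, "'"))
    } else if (is.list(m) && !inherits(m, "synthrig_subject")) {
      e$model <- load_subject(m$mesh, m$sidecar)
    }
    e
  })
  population_spec(entries, cfg$subjects$population_size,
                  cfg$subjects$scale_variation, cfg$subjects$color_variation)
}

resolve_scatterers <- function(cfg) {
  lapply(cfg$environment$scatterers, function(sc) {
    assets <- sc$assets
    if (is.character(assets) && identical(assets, "primitives")) {
      assets <- primitive_asset_library(seed = cfg$debug$seed)
    } else if (is.character(assets)) {
      assets <- stats::setNames(lapply(assets, function(p) normalize_mesh(read_obj(p))),
                                basename(assets))
    }
    scatterer(assets, unlist(sc$size_range %||% c(0.3, 1.5)),
              unlist(sc$count_range %||% c(3, 8)), sc$material %||% NULL)
  })
}

# regeneration iteration of a level at iteration k
last_due <- function(k, period) k - (k %% period)

# Build the fully populated scene for iteration k. Pure in (cfg, k) given
# the resolved population and scatterers; `cache` (an environment) avoids
# recomputing terrain/assets/subjects that did not regenerate.
build_scene <- function(cfg, k, population, scatterers, cache = NULL) {
  p <- cfg$debug$periods
  env_seed <- cfg$debug$seed
  sub_seed <- cfg$debug$subject_seed
  # regenerating a lower level cascades upward: assets cannot outlive the
  # terrain they rest on, nor subjects the assets they stand on
  kt <- last_due(k, p[["terrain"]])
  ka <- max(last_due(k, p[["assets"]]), kt)
  ks <- max(last_due(k, p[["subjects"]]), ka)

  get_cached <- function(tag, iter, build) {
    if (is.null(cache)) return(build())
    key <- paste0(tag, iter)
    if (is.null(cache[[key]])) {
      # drop stale entries of this tag
      for (nm in ls(cache)) if (startsWith(nm, tag)) rm(list = nm, envir = cache)
      cache[[key]] <- build()
    }
    cache[[key]]
  }

  terrain <- get_cached("terrain", kt, function() {
    tc <- cfg$environment$terrain
    map <- generate_rgb_map(tc$resolution, tc$noise, derive_seed(env_seed, "terrain", kt))
    build_terrain(map, tc$extent, tc$amplitude)
  })
  mat_seed <- derive_seed(env_seed, "terrain_mat", kt)
  material <- with_seed(mat_seed, list(color_a = stats::runif(3, 0.1, 0.9),
                                       color_b = stats::runif(3, 0.1, 0.9)))
  assets <- get_cached("assets", ka, function() {
    scatter_assets(scatterers, terrain, derive_seed(env_seed, "assets", ka))
  })
  scene <- list(terrain = terrain, assets = assets, subjects = list(),
                material = material)
  scene$subjects <- get_cached("subjects", ks, function() {
    n_place <- min(cfg$subjects$per_scene %||% length(population), length(population))
    chosen <- with_seed(derive_seed(sub_seed, "choose", ks),
                        sample(seq_along(population), n_place))
    subs <- list()
    for (j in seq_along(chosen)) {
      inst <- population[[chosen[j]]]
      sc2 <- scene; sc2$subjects <- subs
      placement <- place_subject(sc2, inst, derive_seed(sub_seed, "place", ks, j),
                                 retry_cap = cfg$subjects$posing$retry_cap)
      sc2$subjects <- subs
      pose <- pose_subject(inst, placement, sc2, derive_seed(sub_seed, "pose", ks, j),
                           ik_config = cfg$subjects$posing,
                           subject_index = length(subs) + 1L)
      pm <- pose_mesh(inst$model, pose$pose, inst$scale)
      Rc <- euler_to_matrix(placement$rotation)
      ctr <- subject_center_rest(inst)
      wv <- sweep(sweep(pm$vertices, 2, ctr, "-") %*% t(Rc), 2, placement$position, "+")
      wk <- sweep(sweep(pm$keypoints, 2, ctr, "-") %*% t(Rc), 2, placement$position, "+")
      rownames(wk) <- rownames(pm$keypoints)
      subs[[j]] <- list(instance = inst, placement = placement, pose = pose,
                        world_vertices = wv, world_keypoints = wk,
                        proxies = subject_world_proxies(inst, placement, pose$pose),
                        center = colMeans(wv))
    }
    subs
  })
  scene
}

# render one iteration to in-memory passes + annotation
render_iteration <- function(cfg, k, population, scatterers, cache = NULL) {
  scene <- build_scene(cfg, k, population, scatterers, cache)
  cam_seed <- derive_seed(cfg$debug$seed, "camera", k)
  cam_cfg <- cfg$camera
  cam_cfg$resolution <- cfg$general$resolution
  cam <- spawn_camera(scene, cam_seed, cam_cfg)
  lights <- randomize_lights(cfg$environment$lights %||% list(),
                             derive_seed(cfg$debug$seed, "lights", k))
  buffers <- rasterize(scene, cam)
  render <- shade(buffers, lights)
  pp <- with_seed(derive_seed(cfg$debug$seed, "post", k), list(
    temperature = runif1(cfg$post$temperature_range),
    tint = runif1(cfg$post$tint_range),
    saturation = runif1(cfg$post$saturation_range),
    contrast = runif1(cfg$post$contrast_range),
    vignette = runif1(cfg$post$vignette_range),
    grain = runif1(cfg$post$grain_range),
    grain_seed = derive_seed(cfg$debug$seed, "grain", k)))
  render <- post_process(render, pp)
  annotation <- annotate_sample(scene, buffers, k,
                                cfg$general$depth_near, cfg$general$depth_far)
  list(scene = scene, camera = cam, lights = lights, buffers = buffers,
       render = render, annotation = annotation)
}

#' Generate a complete annotated dataset
#'
#' Runs the full randomization loop: terrain, assets, subject placement and
#' posing, and lighting/camera/post-processing are re-randomized at their
#' scheduled periods; every iteration renders the four image passes and
#' writes a sample annotation file, and the run writes one batch file plus
#' a run manifest. Identical config and seed reproduce the dataset bitwise.
#'
#' @param config a config list or YAML path (see [validate_config()]).
#' @return the dataset directory path, invisibly.
#' @export
generate <- function(config) {
  cfg <- validate_config(config)
  pop_spec <- resolve_population(cfg)
  population <- build_population(pop_spec, cfg$debug$subject_seed)
  scatterers <- resolve_scatterers(cfg)
  out <- file.path(cfg$general$output_dir, cfg$general$dataset_name)
  dir.create(file.path(out, "samples"), recursive = TRUE, showWarnings = FALSE)
  batch <- batch_annotation(cfg$general$dataset_name, cfg$general$n_samples,
                            cfg$debug$seed, cfg$general$resolution, population)
  write_batch(batch, file.path(out, "batch.json"))
  cache <- new.env(parent = emptyenv())
  timings <- numeric(cfg$general$n_samples)
  for (k in seq_len(cfg$general$n_samples) - 1L) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      render_iteration(cfg, k, population, scatterers, cache),
      error = function(e) {
        write_manifest(cfg, out, timings, complete = FALSE, failed_at = k)
        stop("generation aborted at sample ", k, ": ", conditionMessage(e))
      })
    write_pass_set(res$buffers, res$render, out, k,
                   cfg$general$depth_near, cfg$general$depth_far,
                   cfg$general$normal_space)
    if (identical(cfg$general$render_format, "jpg")) {
      q <- cfg$general$jpg_quality %||%
        with_seed(derive_seed(cfg$debug$seed, "jpgq", k), stats::runif(1, 0.6, 0.95))
      jpeg::writeJPEG(res$render,
                      file.path(out, "passes", "render", sprintf("%06d.jpg", k)),
                      quality = q)
      unlink(file.path(out, "passes", "render", sprintf("%06d.png", k)))
    }
    write_sample(res$annotation, file.path(out, "samples", sprintf("%06d.json", k)))
    timings[k + 1L] <- proc.time()[["elapsed"]] - t0
  }
  write_manifest(cfg, out, timings, complete = TRUE)
  invisible(out)
}

write_manifest <- function(cfg, out, timings, complete, failed_at = NULL) {
  manifest <- list(
    toolkit = paste0("synthrig ", as.character(utils::packageVersion("synthrig"))),
    complete = complete, failed_at = failed_at,
    per_sample_seconds = round(timings, 3),
    config = unclass(cfg))
  tmp <- file.path(out, ".manifest.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  file.rename(tmp, file.path(out, "manifest.json"))
  invisible(NULL)
}

#' Preview a single iteration without writing a dataset
#'
#' Renders iteration `k` exactly as [generate()] would (same seeds, same
#' schedule), returning the passes and annotation in memory.
#'
#' @param config config list or YAML path.
#' @param iteration 0-based iteration index.
#' @return list with `render`, `buffers`, `annotation`, `scene`, `camera`.
#' @export
preview <- function(config, iteration = 0) {
  cfg <- validate_config(config)
  pop_spec <- resolve_population(cfg)
  population <- build_population(pop_spec, cfg$debug$subject_seed)
  scatterers <- resolve_scatterers(cfg)
  render_iteration(cfg, iteration, population, scatterers)
}
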