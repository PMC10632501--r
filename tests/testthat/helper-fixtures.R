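# Shared fixtures: all built in code at test time.

# small flat-world scene used by placement/posing/rendering tests
flat_scene <- function(extent = 20, amplitude = 0, resolution = 16) {
  map <- generate_rgb_map(resolution, list(octaves = 1, frequency = 2, amplitude = 0),
                          seed = 1)
  terrain <- build_terrain(map, extent, amplitude)
  list(terrain = terrain, assets = list(), subjects = list())
}

# a single-instance wrapper around the built-in articulated subject
stick_instance <- function(scale = 1, id = 1L, antennae = FALSE) {
  structure(list(instance_id = id, class_name = "stick",
                 model = make_stick_subject(antennae = antennae),
                 scale = scale, color_mods = identity_mods_test(),
                 id_color = as.numeric(id_color(id))),
            class = "synthrig_instance")
}

identity_mods_test <- function() {
  list(hue = 0, brightness = 0, contrast = 1, saturation = 1)
}

# a 2-link planar arm: root bone plus two unit links along +x, with a tip
# keypoint; generous symmetric limits unless given
two_link_arm <- function(limits = cbind(rep(-180, 3), rep(180, 3))) {
  seg <- function(center) make_box(c(1, 0.1, 0.1), center = center)
  m <- merge_meshes(list(make_box(c(0.2, 0.2, 0.2)),
                         seg(c(0.5, 0, 0)), seg(c(1.5, 0, 0))))
  new_subject_model(
    class_name = "arm", mesh = m,
    bones = list(
      list(name = "base", parent = NA, rest_offset = c(0, 0, 0)),
      list(name = "link1", parent = "base", rest_offset = c(0, 0, 0)),
      list(name = "link2", parent = "link1", rest_offset = c(1, 0, 0))),
    joints = list(
      list(bone = "base", limits = matrix(0, 3, 2), group = "fixed"),
      list(bone = "link1", limits = limits, group = "mesh_interacting"),
      list(bone = "link2", limits = limits, group = "mesh_interacting")),
    keypoints = list(list(name = "tip", bone = "link2", offset = c(1, 0, 0))),
    vertex_bone = rep(1:3, each = 8))
}

arm_instance <- function(limits = cbind(rep(-180, 3), rep(180, 3))) {
  structure(list(instance_id = 1L, class_name = "arm",
                 model = two_link_arm(limits), scale = 1,
                 color_mods = identity_mods_test(),
                 id_color = as.numeric(id_color(1))),
            class = "synthrig_instance")
}

# generation config small enough for test-time rendering
small_config <- function(n_samples = 2, seed = 7, out = tempfile(), ...) {
  utils::modifyList(list(
    general = list(n_samples = n_samples, resolution = c(128, 128),
                   output_dir = out, dataset_name = "fixture"),
    subjects = list(population_size = 4, per_scene = 3),
    environment = list(terrain = list(resolution = 48, extent = 20,
                                      amplitude = 0.8)),
    debug = list(seed = seed)), list(...))
}
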