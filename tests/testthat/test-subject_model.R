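test_that("the built-in stick subject loads from files with the expected armature", {
  dir <- withr::local_tempdir()
  paths <- write_stick_subject(dir)
  model <- load_subject(paths$mesh, paths$sidecar)
  expect_s3_class(model, "synthrig_subject")
  expect_equal(length(model$bones), 13)
  expect_equal(length(model$chains), 6)
  # every chain ends in a leaf foot bone
  for (ch in model$chains) {
    expect_equal(length(ch), 2)
    tip <- model$bone_names[ch[length(ch)]]
    parents <- vapply(model$bones, function(b) {
      if (is.null(b$parent) || is.na(b$parent)) "" else b$parent
    }, "")
    expect_false(tip %in% parents)
  }
})

test_that("armature validation rejects cycles, orphan vertices and unknown references", {
  subj <- make_stick_subject()
  bones_cycle <- subj$bones
  bones_cycle[[2]]$parent <- bones_cycle[[2]]$name
  expect_error(
    new_subject_model("bad", subj$mesh, bones_cycle, subj$joints,
                      subj$keypoints, subj$vertex_bone),
    "cycle")
  kp_bad <- c(subj$keypoints, list(list(name = "extra", bone = "thorax2",
                                        offset = c(0, 0, 0))))
  expect_error(
    new_subject_model("bad", subj$mesh, subj$bones, subj$joints, kp_bad,
                      subj$vertex_bone),
    "thorax2")
  vb <- subj$vertex_bone
  vb[1] <- 99L
  expect_error(
    new_subject_model("bad", subj$mesh, subj$bones, subj$joints,
                      subj$keypoints, vb),
    "orphan|invalid")
  expect_error(
    new_subject_model("bad", subj$mesh, subj$bones[-1], subj$joints,
                      subj$keypoints, subj$vertex_bone),
    "root|parent")
})

test_that("population class counts follow fractions with largest-remainder correction", {
  models <- list(minor = make_stick_subject(), media = make_stick_subject(),
                 major = make_stick_subject())
  spec <- population_spec(
    list(minor = list(model = models$minor, fraction = 0.2),
         media = list(model = models$media, fraction = 0.6),
         major = list(model = models$major, fraction = 0.2)),
    population_size = 100, scale_variation = 0.33)
  pop <- build_population(spec, seed = 11)
  counts <- table(vapply(pop, `[[`, "", "class_name"))
  expect_equal(as.integer(counts[c("minor", "media", "major")]), c(20, 60, 20))
  expect_equal(length(pop), 100)
  # fractions that do not divide evenly still sum to the population size
  spec2 <- population_spec(
    list(a = list(model = models$minor, fraction = 1 / 3),
         b = list(model = models$media, fraction = 1 / 3),
         c = list(model = models$major, fraction = 1 / 3)),
    population_size = 10, scale_variation = 0)
  pop2 <- build_population(spec2, seed = 1)
  expect_equal(length(pop2), 10)
})

test_that("population sampling is seeded, scale-bounded, and id colors are unique", {
  spec <- population_spec(
    list(stick = list(model = make_stick_subject(), fraction = 1)),
    population_size = 50, scale_variation = 0.33)
  p1 <- build_population(spec, seed = 5)
  p2 <- build_population(spec, seed = 5)
  expect_identical(p1, p2)
  scales <- vapply(p1, `[[`, 0, "scale")
  expect_true(all(scales >= 1 - 0.33 & scales <= 1 + 0.33))
  cols <- t(vapply(p1, `[[`, numeric(3), "id_color"))
  expect_equal(anyDuplicated(cols), 0)
  expect_false(any(rowSums(cols) == 0))
  # zero variation pins every scale at 1
  spec0 <- population_spec(
    list(stick = list(model = make_stick_subject(), fraction = 1)),
    population_size = 5, scale_variation = 0)
  expect_true(all(vapply(build_population(spec0, 1), `[[`, 0, "scale") == 1))
})

test_that("id color mapping is the documented bijection and excludes black", {
  expect_equal(as.numeric(id_color(1)), c(1, 0, 0) / 255)
  expect_equal(as.numeric(id_color(256)), c(0, 1, 0) / 255)
  expect_equal(as.numeric(id_color(65536)), c(0, 0, 1) / 255)
  ids <- c(1, 2, 255, 256, 257, 65535, 65536, 2^24 - 1)
  cols <- id_color(ids)
  expect_equal(anyDuplicated(round(cols * 255)), 0)
  expect_error(id_color(0), "out of")
  expect_error(id_color(2^24), "out of")
})

test_that("color modifiers follow HSV hue rotation and the affine operators", {
  id <- list(hue = 0, brightness = 0, contrast = 1, saturation = 1)
  expect_equal(apply_color_mods(c(0.3, 0.6, 0.9), id), c(0.3, 0.6, 0.9))
  # full hue turn is the identity
  turn <- utils::modifyList(id, list(hue = 360))
  expect_equal(apply_color_mods(c(0.2, 0.5, 0.7), turn), c(0.2, 0.5, 0.7),
               tolerance = 1e-6)
  # pure red rotated +120 degrees is pure green
  expect_equal(apply_color_mods(c(1, 0, 0), utils::modifyList(id, list(hue = 120))),
               c(0, 1, 0), tolerance = 1e-6)
  # brightness and contrast are the documented affine maps
  expect_equal(apply_color_mods(c(0.5, 0.5, 0.5),
                                utils::modifyList(id, list(brightness = 0.2))),
               c(0.7, 0.7, 0.7))
  expect_equal(apply_color_mods(c(0.25, 0.5, 0.75),
                                utils::modifyList(id, list(contrast = 2))),
               c(0, 0.5, 1))
  # clipped to the unit cube
  out <- apply_color_mods(c(0.9, 0.1, 0.5),
                          utils::modifyList(id, list(brightness = 0.5, contrast = 3)))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("forward kinematics is rigid per bone and matches composed rotations", {
  model <- make_stick_subject()
  pose0 <- zero_pose(model)
  rest <- pose_mesh(model, pose0, scale = 1)
  expect_equal(rest$vertices, model$mesh$vertices)
  # uniform scale doubles all pairwise distances
  scaled <- pose_mesh(model, pose0, scale = 2)
  i <- c(1, 10, 50); j <- c(5, 30, 80)
  d1 <- sqrt(rowSums((rest$vertices[i, ] - rest$vertices[j, ])^2))
  d2 <- sqrt(rowSums((scaled$vertices[i, ] - scaled$vertices[j, ])^2))
  expect_equal(d2, 2 * d1)
  # 2-link chain with both joints rotated +90 about z: the tip keypoint
  # lands where hand-composed rotation matrices put it
  arm <- two_link_arm()
  pose <- zero_pose(arm)
  pose$link1 <- c(0, 0, 90)
  pose$link2 <- c(0, 0, 90)
  posed <- pose_mesh(arm, pose, scale = 1)
  R90 <- euler_to_matrix(c(0, 0, 90))
  expected_tip <- as.numeric(R90 %*% (c(1, 0, 0) + R90 %*% c(1, 0, 0)))
  expect_equal(as.numeric(posed$keypoints["tip", ]), expected_tip, tolerance = 1e-9)
  # within-bone pairwise distances survive any admissible pose
  set.seed(42)
  for (rep in 1:5) {
    pose <- zero_pose(model)
    for (nm in names(pose)) pose[[nm]] <- runif(3, -45, 45)
    posed <- pose_mesh(model, pose, scale = 1)
    for (b in sample(seq_along(model$bones), 4)) {
      vi <- which(model$vertex_bone == b)
      if (length(vi) < 2) next
      vi <- vi[1:2]
      d_rest <- sqrt(sum((model$mesh$vertices[vi[1], ] - model$mesh$vertices[vi[2], ])^2))
      d_posed <- sqrt(sum((posed$vertices[vi[1], ] - posed$vertices[vi[2], ])^2))
      expect_equal(d_posed, d_rest, tolerance = 1e-9)
    }
  }
})

test_that("poses outside joint limits are rejected with the offending joint named", {
  model <- make_stick_subject()
  pose <- zero_pose(model)
  pose$leg1_upper <- c(120, 0, 0)   # limits are +/- 90
  expect_error(pose_mesh(model, pose, 1), "leg1_upper")
})

test_that("OBJ round trip preserves geometry and vertex colors", {
  m <- make_pebble(0.5, 0.3, seed = 3, color = c(0.8, 0.4, 0.2))
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, path)
  m2 <- read_obj(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-7)
  expect_equal(m2$triangles, m$triangles)
  expect_equal(m2$colors, m$colors, tolerance = 1e-7)
  expect_error(read_obj(withr::local_tempfile(fileext = ".obj")), "not found")
})
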