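test_that("pinhole projection follows the closed form and flags points behind", {
  cam <- camera_model(position = c(0, 0, 0), rotation = diag(3),
                      focal_length = 50, sensor_width = 64, sensor_height = 64,
                      resolution = c(128, 128))
  # fx = 50 * 128 / 64 = 100 px, principal point (64, 64)
  expect_equal(cam$derived$fx, 100)
  # optical-axis points project to the principal point at any depth
  p <- project(cam, rbind(c(0, 0, 1), c(0, 0, 7)))
  expect_equal(p$x, c(64, 64))
  expect_equal(p$y, c(64, 64))
  # camera-space (1, 0, 2): pixel (64 + 100 * 1/2, 64) at depth 2
  p2 <- project(cam, c(1, 0, 2))
  expect_equal(c(p2$x, p2$y, p2$depth), c(114, 64, 2))
  # behind the camera
  p3 <- project(cam, c(0, 0, -1))
  expect_true(p3$behind)
  # diagonal FOV formula
  expect_equal(cam$derived$fov_diagonal_deg,
               2 * atan(sqrt(64^2 + 64^2) / (2 * 50)) * 180 / pi)
})

test_that("spawned cameras aim at a subject and are seeded", {
  sc <- preview(small_config(seed = 31), 0)$scene
  cam0 <- spawn_camera(sc, seed = 5, config = list(offset_bound = 0,
                                                   resolution = c(128, 128)))
  target <- sc$subjects[[attr(cam0, "subject")]]$center
  pr <- project(cam0, target)
  expect_equal(pr$x, 64, tolerance = 0.5)
  expect_equal(pr$y, 64, tolerance = 0.5)
  # a small offset keeps the subject center inside the image
  cam1 <- spawn_camera(sc, seed = 6, config = list(offset_bound = 5,
                                                   resolution = c(128, 128)))
  pr1 <- project(cam1, sc$subjects[[attr(cam1, "subject")]]$center)
  expect_true(pr1$x >= 0 && pr1$x <= 128 && pr1$y >= 0 && pr1$y <= 128)
  expect_identical(spawn_camera(sc, seed = 9), spawn_camera(sc, seed = 9))
  expect_error(spawn_camera(list(subjects = list()), 1), "no subjects")
})

test_that("the rasterizer covers exactly the predicted pixels of a known triangle", {
  # single triangle facing the camera, in a fake scene
  cam <- camera_model(position = c(0, 0, -5), rotation = diag(3),
                      focal_length = 50, sensor_width = 50, sensor_height = 50,
                      resolution = c(64, 64))
  tri_world <- rbind(c(-1, -1, 0), c(1, -1, 0), c(0, 1, 0))
  scene <- list(
    terrain = NULL, assets = list(),
    subjects = list(list(
      instance = list(model = list(mesh = mesh(tri_world, rbind(1:3))),
                      color_mods = identity_mods_test(),
                      id_color = c(1, 0, 0) / 255, instance_id = 1L),
      world_vertices = tri_world)))
  # bypass terrain: call the rasterizer on hand-built geometry
  g <- list(vertices = tri_world, colors = matrix(0.5, 3, 3),
            triangles = rbind(1:3), id_colors = rbind(c(1, 0, 0) / 255))
  vc <- synthrig:::world_to_camera(cam, g$vertices)
  d <- cam$derived
  out <- synthrig:::rasterize_cpp(vc, g$vertices, g$triangles, g$colors,
                                  g$id_colors, rbind(c(0, 0, -1)), rbind(c(0, 0, -1)),
                                  64, 64, d$fx, d$fy, d$cx, d$cy, 0.05)
  idr <- t(matrix(out$id_r, 64, 64))
  # per-pixel half-space oracle: pixel center inside the projected triangle
  pr <- project(cam, tri_world)
  inside <- function(px, py) {
    x <- px + 0.5; y <- py + 0.5
    v <- cbind(pr$x, pr$y)
    s <- sapply(1:3, function(i) {
      j <- i %% 3 + 1
      (v[j, 1] - v[i, 1]) * (y - v[i, 2]) - (v[j, 2] - v[i, 2]) * (x - v[i, 1])
    })
    all(s >= 0) || all(s <= 0)
  }
  for (px in seq(10, 50, by = 5)) for (py in seq(10, 50, by = 5)) {
    expect_equal(idr[py + 1, px + 1] > 0, inside(px, py),
                 info = sprintf("pixel (%d, %d)", px, py))
  }
  # depth equals the plane distance where covered
  covered <- t(matrix(out$covered, 64, 64)) > 0
  depth <- t(matrix(out$depth, 64, 64))
  expect_equal(unique(round(depth[covered], 9)), 5)
})

test_that("z-buffering keeps the nearer subject at overlapping pixels", {
  cam <- camera_model(position = c(0, 0, -5), rotation = diag(3),
                      focal_length = 50, sensor_width = 50, sensor_height = 50,
                      resolution = c(64, 64))
  tri <- function(z) rbind(c(-1, -1, z), c(1, -1, z), c(0, 1, z))
  g <- list(vertices = rbind(tri(0), tri(1)), colors = matrix(0.5, 6, 3),
            triangles = rbind(1:3, 4:6),
            id_colors = rbind(c(1, 0, 0) / 255, c(2, 0, 0) / 255))
  vc <- synthrig:::world_to_camera(cam, g$vertices)
  d <- cam$derived
  nrm <- rbind(c(0, 0, -1), c(0, 0, -1))
  out <- synthrig:::rasterize_cpp(vc, g$vertices, g$triangles, g$colors,
                                  g$id_colors, nrm, nrm, 64, 64,
                                  d$fx, d$fy, d$cx, d$cy, 0.05)
  idr <- round(t(matrix(out$id_r, 64, 64)) * 255)
  expect_true(all(idr[idr > 0] == 1))   # nearer triangle wins everywhere
})

test_that("an empty scene yields an all-background ID pass", {
  sc <- flat_scene()
  cam <- camera_model(position = c(0, 0, 10),
                      rotation = synthrig:::look_at_rotation(c(0, 0, 10), c(0, 0, 0)),
                      resolution = c(64, 64))
  buf <- rasterize(sc, cam)
  expect_true(all(buf$id == 0))
  expect_true(any(buf$covered))   # terrain still renders
})

test_that("shading follows the Lambertian, fog and exposure formulas", {
  sc <- preview(small_config(seed = 13), 0)
  buf <- sc$buffers
  # ambient-only light: render equals albedo (on covered pixels)
  amb <- list(ambient = 1, directional = list(direction = c(0, 0, -1),
                                              color = c(1, 1, 1), intensity = 0),
              spotlights = list(), fog_density = 0, sky_color = c(0, 0, 0))
  img <- shade(buf, amb, exposure = 0)
  expect_equal(img[, , 1][buf$covered], buf$albedo[, , 1][buf$covered],
               tolerance = 1e-12)
  # a surface normal perpendicular to the light receives nothing directional
  dir_only <- list(ambient = 0,
                   directional = list(direction = c(-1, 0, 0),
                                      color = c(1, 1, 1), intensity = 1),
                   spotlights = list(), fog_density = 0, sky_color = c(0, 0, 0))
  img2 <- shade(buf, dir_only, exposure = 0)
  perp <- abs(buf$normal_world[, , 1]) < 1e-9 & buf$covered
  expect_true(all(img2[, , 1][perp] == 0))
  # fog blends exp(-d * z) of the surface toward the sky
  fog <- list(ambient = 1, directional = list(direction = c(0, 0, -1),
                                              color = c(1, 1, 1), intensity = 0),
              spotlights = list(), fog_density = 0.3, sky_color = c(1, 1, 1))
  img3 <- shade(buf, fog, exposure = 0)
  i <- which(buf$covered, arr.ind = TRUE)[1, ]
  z <- buf$depth[i[1], i[2]]
  a <- buf$albedo[i[1], i[2], 1]
  expect_equal(img3[i[1], i[2], 1], a * exp(-0.3 * z) + (1 - exp(-0.3 * z)),
               tolerance = 1e-12)
  # exposure is a 2^EV gain
  img4 <- shade(buf, amb, exposure = 1)
  expect_equal(img4[, , 2][buf$covered],
               pmin(2 * buf$albedo[, , 2][buf$covered], 1), tolerance = 1e-12)
})

test_that("post-processing implements vignette, grain seeding and identity", {
  img <- array(0.5, c(32, 32, 3))
  expect_identical(post_process(img, list()), img)
  vig <- post_process(img, list(vignette = 0.5))
  # corner pixel attenuated by 1 - 0.5 * (r/rmax)^2 = 0.5; center unchanged
  expect_equal(vig[1, 1, 1], 0.25)
  expect_equal(vig[16, 16, 1], 0.5, tolerance = 0.01)
  g1 <- post_process(img, list(grain = 0.05, grain_seed = 7))
  g2 <- post_process(img, list(grain = 0.05, grain_seed = 7))
  g3 <- post_process(img, list(grain = 0.05, grain_seed = 8))
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
})

test_that("depth encoding round-trips through the 16-bit packed PNG", {
  depth <- matrix(runif(64 * 64, 0.1, 90), 64, 64)
  img <- synthrig:::encode_depth(depth, 0.05, 100)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  back <- decode_depth(png::readPNG(path), 0.05, 100)
  expect_equal(back, depth, tolerance = (100 - 0.05) / 65535)
})
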