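# Scene rasterization into the four co-registered image passes, Lambertian
# shading, and render-pass post-processing.
#
# All pass images are H x W (x 3) arrays with rows = scanlines, matching the
# png package layout. The ID pass background is exactly (0,0,0); depth is
# the camera-plane distance in world units (Inf on background pixels).

buf_mat <- function(v, W, H) t(matrix(v, W, H))

buf_arr3 <- function(a, b, c, W, H) {
  out <- array(0, c(H, W, 3))
  out[, , 1] <- buf_mat(a, W, H)
  out[, , 2] <- buf_mat(b, W, H)
  out[, , 3] <- buf_mat(c, W, H)
  out
}

# Collect world-space geometry of a scene into flat arrays for the
# rasterizer. Subjects carry their instance id color per triangle; terrain
# and assets carry id (0,0,0).
scene_geometry <- function(scene) {
  meshes <- list(); ids <- list()
  tm <- terrain_mesh(scene$terrain, scene$material %||% NULL)
  meshes[[1]] <- tm; ids[[1]] <- c(0, 0, 0)
  for (a in scene$assets) {
    meshes[[length(meshes) + 1L]] <- a$mesh
    ids[[length(ids) + 1L]] <- c(0, 0, 0)
  }
  for (s in scene$subjects) {
    m <- s$instance$model$mesh
    m$vertices <- s$world_vertices
    m$colors <- apply_color_mods(m$colors, s$instance$color_mods)
    meshes[[length(meshes) + 1L]] <- m
    ids[[length(ids) + 1L]] <- s$instance$id_color
  }
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  cols <- do.call(rbind, lapply(meshes, function(m) {
    if (is.null(m$colors)) matrix(0.5, nrow(m$vertices), 3) else m$colors
  }))
  off <- 0L
  tris <- list(); idcol <- list()
  for (k in seq_along(meshes)) {
    tr <- meshes[[k]]$triangles + off
    tris[[k]] <- tr
    idcol[[k]] <- matrix(ids[[k]], nrow(tr), 3, byrow = TRUE)
    off <- off + nrow(meshes[[k]]$vertices)
  }
  list(vertices = verts, colors = cols,
       triangles = do.call(rbind, tris), id_colors = do.call(rbind, idcol))
}

#' Rasterize a scene into geometry buffers
#'
#' Z-buffered rasterization of terrain, assets and posed subjects. The ID
#' buffer holds each subject's unique instance color ((0,0,0) for
#' terrain/assets/background), the depth buffer the camera-plane distance of
#' the nearest surface, and the normal buffers per-face unit normals
#' (oriented toward the camera) in world and view space, encoded later as
#' `(n + 1) / 2`.
#'
#' @param scene scene list (see [generate()]).
#' @param cam a `synthrig_camera`.
#' @return list of buffers: `depth`, `covered`, `id`, `albedo`,
#'   `normal_world`, `normal_view`, `world_pos` (H x W (x 3)), plus `camera`.
#' @export
rasterize <- function(scene, cam) {
  g <- scene_geometry(scene)
  W <- cam$resolution[1]; H <- cam$resolution[2]
  vc <- world_to_camera(cam, g$vertices)
  tr <- g$triangles
  # per-face world normals, oriented toward the camera
  e1 <- g$vertices[tr[, 2], , drop = FALSE] - g$vertices[tr[, 1], , drop = FALSE]
  e2 <- g$vertices[tr[, 3], , drop = FALSE] - g$vertices[tr[, 1], , drop = FALSE]
  nw <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- sqrt(rowSums(nw^2)); nl[nl == 0] <- 1
  nw <- nw / nl
  ctr <- (g$vertices[tr[, 1], , drop = FALSE] + g$vertices[tr[, 2], , drop = FALSE] +
            g$vertices[tr[, 3], , drop = FALSE]) / 3
  toward <- rowSums(nw * sweep(-ctr, 2, cam$position, "+"))
  nw[toward < 0, ] <- -nw[toward < 0, , drop = FALSE]
  nv <- nw %*% cam$rotation
  d <- cam$derived
  out <- rasterize_cpp(vc, g$vertices, tr, g$colors, g$id_colors, nw, nv,
                       W, H, d$fx, d$fy, d$cx, d$cy, 0.05)
  list(
    depth = buf_mat(out$depth, W, H),
    covered = buf_mat(out$covered, W, H) > 0,
    id = buf_arr3(out$id_r, out$id_g, out$id_b, W, H),
    albedo = buf_arr3(out$albedo_r, out$albedo_g, out$albedo_b, W, H),
    normal_world = buf_arr3(out$nw_x, out$nw_y, out$nw_z, W, H),
    normal_view = buf_arr3(out$nv_x, out$nv_y, out$nv_z, W, H),
    world_pos = buf_arr3(out$wp_x, out$wp_y, out$wp_z, W, H),
    camera = cam)
}

#' Shade the geometry buffers into the render pass
#'
#' Lambertian model: ambient plus one directional light plus cone-falloff
#' spotlights, exponential fog attenuation toward the sky color
#' (`exp(-density * depth)` of the surface color survives), and exposure as
#' a `2^EV` gain. Output clipped to `[0, 1]`.
#'
#' @param buffers a [rasterize()] result.
#' @param lights a [randomize_lights()] rig.
#' @param exposure EV offset (defaults to the camera's).
#' @return H x W x 3 render image in `[0, 1]`.
#' @export
shade <- function(buffers, lights, exposure = NULL) {
  H <- nrow(buffers$depth); W <- ncol(buffers$depth)
  alb <- buffers$albedo
  n <- buffers$normal_world
  light <- array(lights$ambient, c(H, W, 3))
  ld <- -lights$directional$direction
  ndotl <- pmax(0, n[, , 1] * ld[1] + n[, , 2] * ld[2] + n[, , 3] * ld[3])
  for (ch in 1:3) {
    light[, , ch] <- light[, , ch] +
      ndotl * lights$directional$intensity * lights$directional$color[ch]
  }
  for (s in lights$spotlights) {
    dx <- buffers$world_pos[, , 1] - s$position[1]
    dy <- buffers$world_pos[, , 2] - s$position[2]
    dz <- buffers$world_pos[, , 3] - s$position[3]
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    dist[dist == 0] <- 1e-9
    ux <- dx / dist; uy <- dy / dist; uz <- dz / dist
    cosang <- ux * s$direction[1] + uy * s$direction[2] + uz * s$direction[3]
    ccone <- cos(deg2rad(s$cone_deg))
    fall <- pmin(pmax((cosang - ccone) / max(1 - ccone, 1e-6), 0), 1)
    diffuse <- pmax(0, -(n[, , 1] * ux + n[, , 2] * uy + n[, , 3] * uz))
    atten <- s$intensity / (1 + 0.05 * dist^2)
    for (ch in 1:3) {
      light[, , ch] <- light[, , ch] + fall * diffuse * atten * s$color[ch]
    }
  }
  img <- alb * light
  # fog: blend toward sky with exp(-density * depth)
  fogf <- exp(-lights$fog_density * buffers$depth)
  fogf[!buffers$covered] <- 0
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * fogf + lights$sky_color[ch] * (1 - fogf)
  }
  ev <- exposure %||% buffers$camera$exposure
  pmin(pmax(img * 2^ev, 0), 1)
}

#' Post-process the render pass
#'
#' Color temperature and tint as channel gains, saturation and contrast as
#' in the subject appearance operators, a radial vignette
#' `1 - strength * (r / r_max)^2`, additive zero-mean Gaussian grain from
#' its own seed, and an optional depth-of-field proxy (Gaussian blur scaled
#' by the inverse f-number). Only the render pass is ever post-processed;
#' ID/depth/normal passes are untouched.
#'
#' @param render H x W x 3 image.
#' @param spec list: `temperature`, `tint` (channel-gain offsets),
#'   `saturation`, `contrast` (multipliers), `vignette` (strength), `grain`
#'   (amplitude), `grain_seed`, `blur_sigma` (px, 0 = off).
#' @return processed image, clipped to `[0, 1]`.
#' @export
post_process <- function(render, spec = list()) {
  cfg <- utils::modifyList(list(temperature = 0, tint = 0, saturation = 1,
                                contrast = 1, vignette = 0, grain = 0,
                                grain_seed = 1, blur_sigma = 0), spec)
  img <- render
  if (cfg$blur_sigma > 0) img <- gaussian_blur(img, cfg$blur_sigma)
  # temperature: warm/cool shift; tint: green/magenta shift
  gains <- c(1 + cfg$temperature, 1 + cfg$tint, 1 - cfg$temperature)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * gains[ch]
  if (cfg$saturation != 1) {
    lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    for (ch in 1:3) img[, , ch] <- lum + (img[, , ch] - lum) * cfg$saturation
  }
  if (cfg$contrast != 1) img <- (img - 0.5) * cfg$contrast + 0.5
  if (cfg$vignette != 0) {
    H <- dim(img)[1]; W <- dim(img)[2]
    yy <- (seq_len(H) - 0.5) - H / 2
    xx <- (seq_len(W) - 0.5) - W / 2
    r2 <- outer(yy^2, xx^2, "+")
    v <- 1 - cfg$vignette * r2 / max(r2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * v
  }
  if (cfg$grain > 0) {
    H <- dim(img)[1]; W <- dim(img)[2]
    noise <- with_seed(cfg$grain_seed, matrix(stats::rnorm(H * W, 0, cfg$grain), H, W))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
  }
  pmin(pmax(img, 0), 1)
}

gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- m * 0
    for (i in seq_along(k)) {
      off <- i - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[i] * (if (along_rows) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    out
  }
  for (ch in 1:3) img[, , ch] <- blur1(blur1(img[, , ch], TRUE), FALSE)
  img
}

# --- pass I/O ----------------------------------------------------------------

encode_normal <- function(n) (n + 1) / 2

#' Write the four image passes of one sample
#'
#' Render as PNG (or JPG-quality-randomized PNG fallback is not provided:
#' render compression is `png` or `jpeg`-style quality only applies to
#' supported writers); ID, depth and normal passes always as uncompressed
#' PNG. Depth is encoded as 16-bit fixed point in the R (high byte) and G
#' (low byte) channels with a linear near/far mapping.
#'
#' @param buffers [rasterize()] buffers.
#' @param render shaded + post-processed render image.
#' @param dir dataset directory (passes/<type>/ created beneath).
#' @param index 0-based sample index (files named `%06d.png`).
#' @param depth_near,depth_far linear depth mapping range (world units).
#' @param normal_space `"world"` or `"view"` for the normal pass file.
#' @return invisibly, the list of file paths.
#' @export
write_pass_set <- function(buffers, render, dir, index,
                           depth_near = 0.05, depth_far = 100,
                           normal_space = "world") {
  name <- sprintf("%06d.png", index)
  paths <- list()
  for (p in c("render", "id", "depth", "normal")) {
    d <- file.path(dir, "passes", p)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    paths[[p]] <- file.path(d, name)
  }
  png::writePNG(render, paths$render)
  png::writePNG(buffers$id, paths$id)
  png::writePNG(encode_depth(buffers$depth, depth_near, depth_far), paths$depth)
  nrm <- if (normal_space == "view") buffers$normal_view else buffers$normal_world
  png::writePNG(encode_normal(nrm), paths$normal)
  invisible(paths)
}

encode_depth <- function(depth, near, far) {
  d <- pmin(pmax(depth, near), far)
  d[!is.finite(depth)] <- far
  q <- round((d - near) / (far - near) * 65535)
  out <- array(0, c(nrow(depth), ncol(depth), 3))
  out[, , 1] <- (q %/% 256) / 255
  out[, , 2] <- (q %% 256) / 255
  out
}

#' Decode a depth pass image back to world units
#' @param img H x W x 3 array from the depth pass PNG.
#' @param near,far the linear mapping recorded in the sample file.
#' @return H x W depth matrix.
#' @export
decode_depth <- function(img, near, far) {
  q <- round(img[, , 1] * 255) * 256 + round(img[, , 2] * 255)
  near + q / 65535 * (far - near)
}
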