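# Ground-truth computation from the pass set (boxes, keypoint visibility,
# occupancy) and the batch/sample annotation files.
#
# Sample JSON schema:
#   {sample_id, camera{position[3], rotation[3], fov_diagonal_deg,
#    view_projection[4][4], depth_near, depth_far},
#    subjects[]{instance_id, class_name, bbox[4], occupancy,
#      keypoints[]{name, xy[2], xyz_cam[3], visibility}}}
# Batch JSON schema:
#   {dataset_name, n_samples, seed, pass_width, pass_height,
#    subjects[]{instance_id, id_color[3], class_name, scale}}

#' Smallest rectangle covering a set of projected keypoints
#'
#' The box is the elementwise min/max over all projected keypoints —
#' including occluded ones — clipped to the image bounds. A box entirely
#' outside the image is flagged empty.
#'
#' @param points_2d n x 2 matrix of pixel coordinates.
#' @param dims `c(W, H)`.
#' @return list `box = c(x_min, y_min, x_max, y_max)`, `empty` flag.
#' @export
compute_bbox <- function(points_2d, dims) {
  p <- matrix(points_2d, ncol = 2)
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) == 0) stop("compute_bbox: no keypoints")
  raw <- c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
  if (raw[3] < 0 || raw[1] > dims[1] || raw[4] < 0 || raw[2] > dims[2]) {
    return(list(box = c(NA_real_, NA_real_, NA_real_, NA_real_), empty = TRUE))
  }
  list(box = c(max(0, raw[1]), max(0, raw[2]),
               min(dims[1], raw[3]), min(dims[2], raw[4])),
       empty = FALSE)
}

#' Keypoint visibility from the ID and depth passes
#'
#' `out_of_frame` when the projected pixel falls outside the image;
#' otherwise `visible` when some pixel in the 3x3 neighborhood carries the
#' subject's id color and the depth pass there is within 1% of the
#' keypoint's camera depth; otherwise `occluded`.
#'
#' @param xy pixel coordinates.
#' @param depth keypoint camera depth.
#' @param id_pass H x W x 3 ID pass.
#' @param depth_pass H x W depth matrix.
#' @param subject_color the subject's id color (RGB in `[0, 1]`).
#' @param depth_tol relative depth tolerance.
#' @return `"visible"`, `"occluded"` or `"out_of_frame"`.
#' @export
keypoint_visibility <- function(xy, depth, id_pass, depth_pass, subject_color,
                                depth_tol = 0.01) {
  H <- nrow(depth_pass); W <- ncol(depth_pass)
  px <- floor(xy[1]); py <- floor(xy[2])
  if (is.na(px) || is.na(py) || px < 0 || px >= W || py < 0 || py >= H || depth <= 0) {
    return("out_of_frame")
  }
  for (dy in -1:1) for (dx in -1:1) {
    x <- px + dx; y <- py + dy
    if (x < 0 || x >= W || y < 0 || y >= H) next
    r <- y + 1L; c <- x + 1L
    same <- all(abs(id_pass[r, c, ] - subject_color) < 1 / 510)
    if (same && is.finite(depth_pass[r, c]) &&
        abs(depth_pass[r, c] - depth) <= depth_tol * depth) {
      return("visible")
    }
  }
  "occluded"
}

#' Subject occupancy within its bounding box
#'
#' Fraction of the box's pixels carrying the subject's id color.
#'
#' @param id_pass H x W x 3 ID pass.
#' @param box `c(x_min, y_min, x_max, y_max)` pixel box.
#' @param subject_color RGB id color.
#' @return fraction in `[0, 1]`.
#' @export
occupancy <- function(id_pass, box, subject_color) {
  if (any(is.na(box))) stop("occupancy: empty box")
  W <- dim(id_pass)[2]; H <- dim(id_pass)[1]
  x0 <- max(0L, floor(box[1])); y0 <- max(0L, floor(box[2]))
  x1 <- min(W - 1L, ceiling(box[3]) - 1L); x1 <- max(x1, x0)
  y1 <- min(H - 1L, ceiling(box[4]) - 1L); y1 <- max(y1, y0)
  rows <- (y0:y1) + 1L; cols <- (x0:x1) + 1L
  sub <- id_pass[rows, cols, , drop = FALSE]
  hit <- abs(sub[, , 1] - subject_color[1]) < 1 / 510 &
    abs(sub[, , 2] - subject_color[2]) < 1 / 510 &
    abs(sub[, , 3] - subject_color[3]) < 1 / 510
  sum(hit) / (length(rows) * length(cols))
}

# count of id-colored pixels anywhere in the pass
id_pixel_count <- function(id_pass, subject_color) {
  hit <- abs(id_pass[, , 1] - subject_color[1]) < 1 / 510 &
    abs(id_pass[, , 2] - subject_color[2]) < 1 / 510 &
    abs(id_pass[, , 3] - subject_color[3]) < 1 / 510
  sum(hit)
}

#' Build the annotation record for one rendered sample
#'
#' @param scene scene list with posed subjects.
#' @param buffers [rasterize()] buffers.
#' @param sample_id 0-based sample index.
#' @param depth_near,depth_far depth-pass mapping.
#' @return a `synthrig_sample` annotation list (see the schema above).
#' @export
annotate_sample <- function(scene, buffers, sample_id,
                            depth_near = 0.05, depth_far = 100) {
  cam <- buffers$camera
  W <- cam$resolution[1]; H <- cam$resolution[2]
  depth_q <- quantize_depth_like_pass(buffers$depth, depth_near, depth_far)
  subjects <- lapply(scene$subjects, function(s) {
    kp <- s$world_keypoints
    pr <- project(cam, kp)
    xyz_cam <- world_to_camera(cam, kp)
    bb <- if (all(is.na(pr$x))) {
      # subject entirely behind the camera
      list(box = rep(NA_real_, 4), empty = TRUE)
    } else {
      compute_bbox(cbind(pr$x, pr$y), c(W, H))
    }
    vis <- vapply(seq_len(nrow(kp)), function(i) {
      if (pr$behind[i] || is.na(pr$x[i])) return("out_of_frame")
      keypoint_visibility(c(pr$x[i], pr$y[i]), pr$depth[i], buffers$id,
                          depth_q, s$instance$id_color)
    }, "")
    occ <- if (bb$empty) 0 else occupancy(buffers$id, bb$box, s$instance$id_color)
    list(instance_id = s$instance$instance_id,
         class_name = s$instance$class_name,
         bbox = bb$box, occupancy = occ,
         keypoints = lapply(seq_len(nrow(kp)), function(i) list(
           name = rownames(kp)[i],
           xy = c(pr$x[i], pr$y[i]),
           xyz_cam = as.numeric(xyz_cam[i, ]),
           visibility = vis[i])))
  })
  cam_rot <- rotation_to_euler(cam$rotation)
  structure(list(
    sample_id = sample_id,
    camera = list(position = cam$position, rotation = cam_rot,
                  fov_diagonal_deg = cam$derived$fov_diagonal_deg,
                  view_projection = cam$derived$view_projection,
                  intrinsics = c(fx = cam$derived$fx, fy = cam$derived$fy,
                                 cx = cam$derived$cx, cy = cam$derived$cy),
                  depth_near = depth_near, depth_far = depth_far),
    subjects = subjects), class = "synthrig_sample")
}

# the visibility check compares against depth as the 16-bit pass stores it
quantize_depth_like_pass <- function(depth, near, far) {
  d <- pmin(pmax(depth, near), far)
  d[!is.finite(depth)] <- far
  near + round((d - near) / (far - near) * 65535) / 65535 * (far - near)
}

# recover XYZ euler angles (degrees) from a camera-to-world rotation matrix
rotation_to_euler <- function(R) {
  # R = Rz Ry Rx
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  y <- asin(sy)
  if (abs(cos(y)) > 1e-9) {
    x <- atan2(R[3, 2], R[3, 3])
    z <- atan2(R[2, 1], R[1, 1])
  } else {
    x <- atan2(-R[2, 3], R[2, 2])
    z <- 0
  }
  c(x, y, z) * 180 / pi
}

# --- sample file I/O ---------------------------------------------------------

#' Write a sample annotation file
#' @param annotation a [annotate_sample()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(annotation, path) {
  out <- list(
    sample_id = annotation$sample_id,
    camera = list(
      position = as.numeric(annotation$camera$position),
      rotation = as.numeric(annotation$camera$rotation),
      fov_diagonal_deg = annotation$camera$fov_diagonal_deg,
      view_projection = unname(apply(annotation$camera$view_projection, 1,
                                     as.numeric, simplify = FALSE)),
      intrinsics = as.list(annotation$camera$intrinsics),
      depth_near = annotation$camera$depth_near,
      depth_far = annotation$camera$depth_far),
    subjects = lapply(annotation$subjects, function(s) list(
      instance_id = s$instance_id, class_name = s$class_name,
      bbox = as.numeric(s$bbox), occupancy = s$occupancy,
      keypoints = lapply(s$keypoints, function(k) list(
        name = k$name, xy = as.numeric(k$xy),
        xyz_cam = as.numeric(k$xyz_cam), visibility = k$visibility)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17), na = "null",
                       pretty = TRUE)
  invisible(path)
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]])) stop("parse error: missing field '", field, "' in ", where)
  x[[field]]
}

#' Read a sample annotation file
#' @param path JSON path written by [write_sample()].
#' @return a `synthrig_sample`.
#' @export
read_sample <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  cam <- need_field(j, "camera", "sample file")
  vp <- need_field(cam, "view_projection", "camera")
  if (length(vp) != 4 || any(vapply(vp, length, 0L) != 4)) {
    stop("parse error: view_projection must be a 4x4 matrix")
  }
  num <- function(x) as.numeric(unlist(x))
  # JSON null (written for NA) must come back as NA, preserving length
  num_na <- function(x) {
    vapply(x, function(e) if (is.null(e)) NA_real_ else as.numeric(e), 0)
  }
  structure(list(
    sample_id = need_field(j, "sample_id", "sample file"),
    camera = list(
      position = num(need_field(cam, "position", "camera")),
      rotation = num(need_field(cam, "rotation", "camera")),
      fov_diagonal_deg = cam$fov_diagonal_deg,
      view_projection = do.call(rbind, lapply(vp, num)),
      intrinsics = unlist(cam$intrinsics),
      depth_near = cam$depth_near, depth_far = cam$depth_far),
    subjects = lapply(need_field(j, "subjects", "sample file"), function(s) list(
      instance_id = need_field(s, "instance_id", "subject"),
      class_name = s$class_name,
      bbox = num_na(s$bbox), occupancy = s$occupancy,
      keypoints = lapply(s$keypoints, function(k) list(
        name = k$name, xy = num_na(k$xy), xyz_cam = num(k$xyz_cam),
        visibility = k$visibility))))), class = "synthrig_sample")
}

# --- batch file I/O ----------------------------------------------------------

#' Build a batch annotation
#' @param dataset_name dataset label.
#' @param n_samples number of samples.
#' @param seed master seed (recorded verbatim).
#' @param pass_dims `c(W, H)`.
#' @param population list of `synthrig_instance`.
#' @return a `synthrig_batch`.
#' @export
batch_annotation <- function(dataset_name, n_samples, seed, pass_dims, population) {
  structure(list(
    dataset_name = dataset_name, n_samples = n_samples, seed = seed,
    pass_width = pass_dims[1], pass_height = pass_dims[2],
    subjects = lapply(population, function(p) list(
      instance_id = p$instance_id, id_color = as.numeric(p$id_color),
      class_name = p$class_name, scale = p$scale))),
    class = "synthrig_batch")
}

validate_batch <- function(batch) {
  ids <- vapply(batch$subjects, `[[`, 0, "instance_id")
  if (anyDuplicated(ids)) stop("validation error: duplicate instance_id in batch")
  for (s in batch$subjects) {
    if (all(s$id_color == 0)) {
      stop("validation error: id_color (0,0,0) is reserved for background")
    }
  }
  invisible(batch)
}

#' Write / read the batch annotation file
#' @param batch a [batch_annotation()].
#' @param path JSON path.
#' @return `path` / a `synthrig_batch`.
#' @export
write_batch <- function(batch, path) {
  validate_batch(batch)
  jsonlite::write_json(unclass(batch), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_batch
#' @export
read_batch <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("dataset_name", "n_samples", "seed", "pass_width", "pass_height",
                "subjects")) {
    need_field(j, key, "batch file")
  }
  b <- structure(list(
    dataset_name = j$dataset_name, n_samples = j$n_samples, seed = j$seed,
    pass_width = j$pass_width, pass_height = j$pass_height,
    subjects = lapply(j$subjects, function(s) list(
      instance_id = s$instance_id, id_color = as.numeric(unlist(s$id_color)),
      class_name = s$class_name, scale = s$scale))), class = "synthrig_batch")
  validate_batch(b)
  b
}
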