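# Dataset exporters: YOLO boxes, COCO (detection + keypoints + masks), flat
# keypoint tables, segmentation label maps, and the camera-aware 3D pose
# format. All exporters are read-only over the dataset directory.

#' Export configuration
#'
#' @param exclude_occluded drop occluded keypoints (written as empty /
#'   v = 1 depending on the target family).
#' @param exclude_hidden_subjects drop subjects with occupancy 0.
#' @param split train fraction in `(0, 1)`, or `NULL` for no split.
#' @param split_seed seed for the split shuffle.
#' @param mask_encoding `"per_pixel"`, `"polygon"` or `"rle"`.
#' @return an `synthrig_export_config`.
#' @export
export_config <- function(exclude_occluded = FALSE, exclude_hidden_subjects = TRUE,
                          split = NULL, split_seed = 1, mask_encoding = "rle") {
  if (!is.null(split) && (split <= 0 || split >= 1)) {
    stop("split fraction must be in the open interval (0, 1)")
  }
  if (!mask_encoding %in% c("per_pixel", "polygon", "rle")) {
    stop("unknown mask encoding '", mask_encoding, "'")
  }
  structure(list(exclude_occluded = exclude_occluded,
                 exclude_hidden_subjects = exclude_hidden_subjects,
                 split = split, split_seed = split_seed,
                 mask_encoding = mask_encoding),
            class = "synthrig_export_config")
}

# list sample files of a dataset directory, index-ordered
dataset_samples <- function(dataset_dir) {
  files <- sort(list.files(file.path(dataset_dir, "samples"), "\\.json$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no sample files found under ", dataset_dir)
  files
}

dataset_classes <- function(dataset_dir) {
  batch <- read_batch(file.path(dataset_dir, "batch.json"))
  sort(unique(vapply(batch$subjects, `[[`, "", "class_name")))
}

read_id_pass <- function(dataset_dir, index) {
  png::readPNG(file.path(dataset_dir, "passes", "id", sprintf("%06d.png", index)))
}

#' Split a dataset into train and validation lists
#'
#' Deterministic shuffled split: disjoint and exhaustive over the sample
#' indices.
#'
#' @param n_samples number of samples (or a dataset directory path).
#' @param fraction train fraction in `(0, 1)`.
#' @param seed shuffle seed.
#' @return list `train`, `validation` of 0-based sample indices.
#' @export
split_dataset <- function(n_samples, fraction, seed = 1) {
  if (is.character(n_samples)) n_samples <- length(dataset_samples(n_samples))
  if (fraction <= 0 || fraction >= 1) {
    stop("split fraction must be in the open interval (0, 1)")
  }
  idx <- with_seed(seed, sample.int(n_samples)) - 1L
  n_train <- round(fraction * n_samples)
  list(train = sort(idx[seq_len(n_train)]),
       validation = sort(idx[setdiff(seq_len(n_samples), seq_len(n_train))]))
}

retained_subjects <- function(sample, config) {
  Filter(function(s) {
    if (any(is.na(s$bbox))) return(FALSE)
    if (config$exclude_hidden_subjects && s$occupancy == 0) return(FALSE)
    TRUE
  }, sample$subjects)
}

#' Export a dataset to YOLO (darknet) labels
#'
#' One text file per image with one `class cx cy w h` line per retained
#' subject, normalized to `[0, 1]` at 6-decimal precision, plus
#' `classes.txt` and an image list file. Empty-box subjects are skipped and
#' counted.
#'
#' @param dataset_dir dataset directory written by [generate()].
#' @param out_dir output directory.
#' @param config an [export_config()].
#' @return list `label_files`, `classes`, `skipped` (count), invisibly.
#' @export
to_yolo <- function(dataset_dir, out_dir, config = export_config()) {
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  batch <- read_batch(file.path(dataset_dir, "batch.json"))
  W <- batch$pass_width; H <- batch$pass_height
  classes <- dataset_classes(dataset_dir)
  skipped <- 0L
  label_files <- character(0)
  image_list <- character(0)
  for (f in dataset_samples(dataset_dir)) {
    smp <- read_sample(f)
    lines <- character(0)
    for (s in smp$subjects) {
      keep <- length(retained_subjects(list(subjects = list(s)), config)) == 1
      if (!keep) { skipped <- skipped + 1L; next }
      b <- s$bbox
      lines <- c(lines, sprintf("%d %.6f %.6f %.6f %.6f",
                                match(s$class_name, classes) - 1L,
                                (b[1] + b[3]) / 2 / W, (b[2] + b[4]) / 2 / H,
                                (b[3] - b[1]) / W, (b[4] - b[2]) / H))
    }
    stem <- sprintf("%06d", smp$sample_id)
    lf <- file.path(out_dir, "labels", paste0(stem, ".txt"))
    writeLines(lines, lf)
    label_files <- c(label_files, lf)
    image_list <- c(image_list, file.path("passes", "render", paste0(stem, ".png")))
  }
  writeLines(classes, file.path(out_dir, "classes.txt"))
  writeLines(image_list, file.path(out_dir, "images.txt"))
  invisible(list(label_files = label_files, classes = classes, skipped = skipped))
}

#' Read YOLO labels back as pixel boxes
#' @param label_file a YOLO label file.
#' @param dims image `c(W, H)`.
#' @return data.frame `class_index`, `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
read_yolo <- function(label_file, dims) {
  lines <- readLines(label_file)
  if (length(lines) == 0) {
    return(data.frame(class_index = integer(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0), y_max = numeric(0)))
  }
  m <- do.call(rbind, lapply(strsplit(lines, " "), as.numeric))
  data.frame(class_index = as.integer(m[, 1]),
             x_min = (m[, 2] - m[, 4] / 2) * dims[1],
             y_min = (m[, 3] - m[, 5] / 2) * dims[2],
             x_max = (m[, 2] + m[, 4] / 2) * dims[1],
             y_max = (m[, 3] + m[, 5] / 2) * dims[2])
}

# --- masks -------------------------------------------------------------------

# binary mask (H x W logical) of one subject from the id pass
subject_mask <- function(id_pass, color) {
  abs(id_pass[, , 1] - color[1]) < 1 / 510 &
    abs(id_pass[, , 2] - color[2]) < 1 / 510 &
    abs(id_pass[, , 3] - color[3]) < 1 / 510
}

#' COCO uncompressed RLE of a binary mask
#'
#' Column-major run lengths, starting with the count of background pixels
#' (possibly zero), matching the COCO uncompressed RLE convention.
#'
#' @param mask H x W logical matrix.
#' @return list `size = c(H, W)`, `counts` integer vector.
#' @export
mask_to_rle <- function(mask) {
  v <- as.integer(mask)           # column-major flattening
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1) counts <- c(0L, counts)
  list(size = dim(mask), counts = as.integer(counts))
}

#' Decode a COCO uncompressed RLE back to a mask
#' @param rle list with `size`, `counts`.
#' @return H x W logical matrix.
#' @export
rle_to_mask <- function(rle) {
  vals <- rep(rep(c(0L, 1L), length.out = length(rle$counts)), rle$counts)
  matrix(vals == 1L, rle$size[1], rle$size[2])
}

# Trace the outer contour of a binary mask with marching squares on the
# pixel-corner grid, then simplify with Douglas-Peucker at `tol` pixels.
# Returns a list of polygons (x0 y0 x1 y1 ... in pixel coordinates).
mask_to_polygons <- function(mask, tol = 1) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  # horizontal and vertical boundary edges between corner nodes
  # corner (i, j) = lattice point at pixel coordinates (x = j - 1, y = i - 1)
  edges <- list()
  for (i in 1:(H + 1)) for (j in 1:(W + 1)) {
    # edge below row boundary between (i,j)-(i,j+1) exists where cell above
    # differs from cell below
    if (j <= W && pad[i, j + 1] != pad[i + 1, j + 1]) {
      edges[[length(edges) + 1L]] <- c(j - 1, i - 1, j, i - 1)
    }
    if (i <= H && pad[i + 1, j] != pad[i + 1, j + 1]) {
      edges[[length(edges) + 1L]] <- c(j - 1, i - 1, j - 1, i)
    }
  }
  if (length(edges) == 0) return(list())
  em <- do.call(rbind, edges)
  key <- function(x, y) paste(x, y)
  adj <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(em))) {
    k1 <- key(em[r, 1], em[r, 2]); k2 <- key(em[r, 3], em[r, 4])
    adj[[k1]] <- c(adj[[k1]], r); adj[[k2]] <- c(adj[[k2]], r)
  }
  used <- logical(nrow(em))
  polys <- list()
  for (start in seq_len(nrow(em))) {
    if (used[start]) next
    path <- list(em[start, 1:2], em[start, 3:4])
    used[start] <- TRUE
    repeat {
      tail <- path[[length(path)]]
      cand <- adj[[key(tail[1], tail[2])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      e <- cand[1]; used[e] <- TRUE
      nxt <- if (all(em[e, 1:2] == tail)) em[e, 3:4] else em[e, 1:2]
      if (all(nxt == path[[1]])) break
      path[[length(path) + 1L]] <- nxt
    }
    pts <- do.call(rbind, path)
    if (nrow(pts) >= 3) polys[[length(polys) + 1L]] <- simplify_polygon(pts, tol)
  }
  polys
}

simplify_polygon <- function(pts, tol) {
  if (tol <= 0 || nrow(pts) <= 4) return(pts)
  dp <- function(pts) {
    n <- nrow(pts)
    if (n <= 2) return(pts)
    a <- pts[1, ]; b <- pts[n, ]
    ab <- b - a; len <- sqrt(sum(ab^2))
    d <- if (len < 1e-12) {
      sqrt(rowSums(sweep(pts, 2, a, "-")^2))
    } else {
      abs((pts[, 1] - a[1]) * ab[2] - (pts[, 2] - a[2]) * ab[1]) / len
    }
    i <- which.max(d)
    if (d[i] <= tol) return(pts[c(1, n), , drop = FALSE])
    left <- dp(pts[1:i, , drop = FALSE])
    right <- dp(pts[i:n, , drop = FALSE])
    rbind(left[-nrow(left), , drop = FALSE], right)
  }
  out <- dp(pts)
  if (nrow(out) < 3) pts else out
}

visibility_code <- function(v) {
  switch(v, visible = 2L, occluded = 1L, out_of_frame = 0L, 0L)
}

#' Export a dataset to a COCO JSON
#'
#' Standard COCO dictionaries (`images`, `annotations`, `categories` with
#' per-category keypoint name lists). Boxes are `[x, y, w, h]`; keypoints
#' are flattened `(x, y, v)` triplets with v = 2 visible, 1 occluded,
#' 0 out-of-frame; segmentations follow the configured encoding (`"rle"`
#' uncompressed RLE or `"polygon"`); `area` is the subject's id-pass pixel
#' count.
#'
#' @param dataset_dir dataset directory.
#' @param out_file output JSON path.
#' @param config an [export_config()].
#' @return the COCO list, invisibly.
#' @export
to_coco <- function(dataset_dir, out_file, config = export_config()) {
  if (config$mask_encoding == "per_pixel") {
    stop("unknown mask encoding for COCO: use 'rle' or 'polygon' ",
         "(per-pixel maps are written by to_segmentation_maps)")
  }
  batch <- read_batch(file.path(dataset_dir, "batch.json"))
  classes <- dataset_classes(dataset_dir)
  files <- dataset_samples(dataset_dir)
  first <- read_sample(files[1])
  kp_names <- if (length(first$subjects) > 0) {
    vapply(first$subjects[[1]]$keypoints, `[[`, "", "name")
  } else character(0)
  images <- list(); annotations <- list()
  ann_id <- 0L
  for (f in files) {
    smp <- read_sample(f)
    img_id <- smp$sample_id
    images[[length(images) + 1L]] <- list(
      id = img_id, width = batch$pass_width, height = batch$pass_height,
      file_name = sprintf("passes/render/%06d.png", img_id))
    id_pass <- read_id_pass(dataset_dir, img_id)
    for (s in retained_subjects(smp, config)) {
      color <- batch$subjects[[which(vapply(batch$subjects, `[[`, 0, "instance_id") ==
                                       s$instance_id)]]$id_color
      mask <- subject_mask(id_pass, color)
      area <- sum(mask)
      seg <- if (config$mask_encoding == "rle") {
        r <- mask_to_rle(mask)
        list(size = as.integer(r$size), counts = r$counts)
      } else {
        polys <- mask_to_polygons(mask, tol = 1)
        lapply(polys, function(p) as.numeric(t(p)))
      }
      kps <- unlist(lapply(s$keypoints, function(k) {
        v <- visibility_code(k$visibility)
        if (config$exclude_occluded && v == 1L) v <- 0L
        if (v == 0L) c(0, 0, 0) else c(k$xy[1], k$xy[2], v)
      }))
      ann_id <- ann_id + 1L
      b <- s$bbox
      annotations[[length(annotations) + 1L]] <- list(
        id = ann_id, image_id = img_id,
        category_id = match(s$class_name, classes),
        bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
        area = area, iscrowd = 0L,
        segmentation = seg,
        keypoints = as.numeric(kps),
        num_keypoints = sum(vapply(s$keypoints, function(k)
          visibility_code(k$visibility) > 0, TRUE)))
    }
  }
  coco <- list(
    images = images,
    annotations = annotations,
    categories = lapply(seq_along(classes), function(i) list(
      id = i, name = classes[i], supercategory = "animal",
      keypoints = as.list(kp_names))))
  jsonlite::write_json(coco, out_file, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  invisible(coco)
}

#' Export a dataset as a flat keypoint table
#'
#' Wide CSV with two header rows (keypoint name; coordinate), one data row
#' per (image, instance): columns `<kp>_x`, `<kp>_y`, `<kp>_likelihood`
#' with likelihood 1.0 for visible points. When occluded exclusion is on,
#' excluded keypoints have empty cells. A skeleton file lists the keypoint
#' order and armature bone connections.
#'
#' @param dataset_dir dataset directory.
#' @param out_dir output directory (`keypoints.csv` + `skeleton.txt`).
#' @param config an [export_config()].
#' @param skeleton optional list of `c(parent_keypoint, child_keypoint)`
#'   pairs; defaults to chaining keypoints in order.
#' @return path of the CSV, invisibly.
#' @export
to_keypoint_table <- function(dataset_dir, out_dir, config = export_config(),
                              skeleton = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- dataset_samples(dataset_dir)
  first <- read_sample(files[1])
  if (length(first$subjects) == 0) stop("dataset has no subjects")
  kp_names <- vapply(first$subjects[[1]]$keypoints, `[[`, "", "name")
  header1 <- c("image", "instance",
               rep(kp_names, each = 3))
  header2 <- c("", "", rep(c("x", "y", "likelihood"), length(kp_names)))
  rows <- list(paste(header1, collapse = ","), paste(header2, collapse = ","))
  for (f in files) {
    smp <- read_sample(f)
    for (s in retained_subjects(smp, config)) {
      cells <- c(sprintf("%06d", smp$sample_id), as.character(s$instance_id))
      for (k in s$keypoints) {
        excl <- (config$exclude_occluded && k$visibility != "visible") ||
          k$visibility == "out_of_frame"
        if (excl || any(is.na(k$xy))) {
          cells <- c(cells, "", "", "")
        } else {
          cells <- c(cells, sprintf("%.17g", k$xy[1]), sprintf("%.17g", k$xy[2]), "1.0")
        }
      }
      rows[[length(rows) + 1L]] <- paste(cells, collapse = ",")
    }
  }
  csv <- file.path(out_dir, "keypoints.csv")
  writeLines(unlist(rows), csv)
  if (is.null(skeleton)) {
    skeleton <- if (length(kp_names) > 1) {
      lapply(seq_len(length(kp_names) - 1), function(i) kp_names[c(i, i + 1)])
    } else list()
  }
  writeLines(c(paste(kp_names, collapse = ","),
               vapply(skeleton, paste, "", collapse = "-")),
             file.path(out_dir, "skeleton.txt"))
  invisible(csv)
}

#' Read a keypoint table back
#' @param csv path written by [to_keypoint_table()].
#' @return long data.frame `image`, `instance`, `keypoint`, `x`, `y`,
#'   `likelihood` (NA for empty cells).
#' @export
read_keypoint_table <- function(csv) {
  lines <- readLines(csv)
  h1 <- strsplit(lines[1], ",")[[1]]
  kp_names <- unique(h1[-(1:2)])
  out <- list()
  for (ln in lines[-(1:2)]) {
    cells <- strsplit(ln, ",", fixed = TRUE)[[1]]
    length(cells) <- 2 + 3 * length(kp_names)
    for (i in seq_along(kp_names)) {
      o <- 2 + (i - 1) * 3
      out[[length(out) + 1L]] <- data.frame(
        image = cells[1], instance = as.integer(cells[2]), keypoint = kp_names[i],
        x = suppressWarnings(as.numeric(cells[o + 1])),
        y = suppressWarnings(as.numeric(cells[o + 2])),
        likelihood = suppressWarnings(as.numeric(cells[o + 3])))
    }
  }
  do.call(rbind, out)
}

#' Export per-image segmentation label maps
#'
#' 8-bit single-channel PNGs: 0 background, 1 any subject (binary mode), or
#' per-class labels 1..K when `per_class = TRUE`.
#'
#' @param dataset_dir dataset directory.
#' @param out_dir output directory.
#' @param per_class map each subject class to its own label index.
#' @return character vector of written label map paths, invisibly.
#' @export
to_segmentation_maps <- function(dataset_dir, out_dir, per_class = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  batch <- read_batch(file.path(dataset_dir, "batch.json"))
  classes <- dataset_classes(dataset_dir)
  if (per_class && length(classes) > 255) stop("more than 255 classes")
  paths <- character(0)
  for (f in dataset_samples(dataset_dir)) {
    smp <- read_sample(f)
    id_pass <- read_id_pass(dataset_dir, smp$sample_id)
    lab <- matrix(0L, nrow(id_pass[, , 1]), ncol(id_pass[, , 1]))
    for (bs in batch$subjects) {
      m <- subject_mask(id_pass, bs$id_color)
      lab[m] <- if (per_class) match(bs$class_name, classes) else 1L
    }
    p <- file.path(out_dir, sprintf("%06d.png", smp$sample_id))
    png::writePNG(lab / 255, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a segmentation label map
#' @param path label-map PNG.
#' @return integer matrix of labels.
#' @export
read_segmentation_map <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Export the camera-aware 3D pose format
#'
#' Per sample: intrinsic matrix, camera position/rotation, view-projection
#' matrix, and per-subject camera-relative 3D keypoints, lossless with
#' respect to the sample files.
#'
#' @param dataset_dir dataset directory.
#' @param out_file output JSON path.
#' @return the exported list, invisibly.
#' @export
to_pose3d <- function(dataset_dir, out_file) {
  samples <- lapply(dataset_samples(dataset_dir), function(f) {
    smp <- read_sample(f)
    K <- smp$camera$intrinsics
    list(sample_id = smp$sample_id,
         intrinsics = list(fx = K[["fx"]], fy = K[["fy"]],
                           cx = K[["cx"]], cy = K[["cy"]]),
         camera_position = smp$camera$position,
         camera_rotation = smp$camera$rotation,
         view_projection = unname(apply(smp$camera$view_projection, 1,
                                        as.numeric, simplify = FALSE)),
         subjects = lapply(smp$subjects, function(s) list(
           instance_id = s$instance_id,
           keypoints = lapply(s$keypoints, function(k) list(
             name = k$name, xyz_cam = k$xyz_cam, xy = k$xy,
             visibility = k$visibility)))))
  })
  out <- list(format = "synthrig_pose3d", n_samples = length(samples),
              samples = samples)
  jsonlite::write_json(out, out_file, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = FALSE)
  invisible(out)
}
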