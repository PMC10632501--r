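# one small generated dataset shared by all exporter tests
local_dataset <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      cfg <- small_config(n_samples = 3, seed = 19)
      dir <<- generate(cfg)
    }
    dir
  }
})

test_that("YOLO export normalizes boxes and round-trips within quantization", {
  ds <- local_dataset()
  out <- withr::local_tempdir()
  res <- to_yolo(ds, out, export_config())
  expect_true(file.exists(file.path(out, "classes.txt")))
  batch <- read_batch(file.path(ds, "batch.json"))
  dims <- c(batch$pass_width, batch$pass_height)
  n_lines <- 0L
  for (f in dataset_samples(ds)) {
    smp <- read_sample(f)
    lf <- file.path(out, "labels", sprintf("%06d.txt", smp$sample_id))
    got <- read_yolo(lf, dims)
    n_lines <- n_lines + nrow(got)
    kept <- Filter(function(s) !any(is.na(s$bbox)) && s$occupancy > 0, smp$subjects)
    expect_equal(nrow(got), length(kept))
    for (i in seq_along(kept)) {
      expect_equal(as.numeric(got[i, 2:5]), kept[[i]]$bbox, tolerance = 0.5)
    }
  }
  # lines + skips account for every subject record
  total_records <- sum(vapply(dataset_samples(ds), function(f) {
    length(read_sample(f)$subjects)
  }, 0L))
  expect_equal(n_lines + res$skipped, total_records)
  # hand-checked normalization example
  tmp <- withr::local_tempdir()
  d2 <- file.path(tmp, "mini")
  dir.create(file.path(d2, "samples"), recursive = TRUE)
  pop <- build_population(population_spec(
    list(stick = list(model = make_stick_subject(), fraction = 1)), 1, 0), 1)
  write_batch(batch_annotation("mini", 1, 1, c(1000, 1000), pop),
              file.path(d2, "batch.json"))
  ann <- list(sample_id = 0L,
              camera = list(position = c(0, 0, 0), rotation = c(0, 0, 0),
                            fov_diagonal_deg = 60, view_projection = diag(4),
                            intrinsics = c(fx = 1, fy = 1, cx = 0, cy = 0),
                            depth_near = 0.05, depth_far = 100),
              subjects = list(list(instance_id = 1L, class_name = "stick",
                                   bbox = c(100, 200, 300, 400), occupancy = 0.5,
                                   keypoints = list())))
  class(ann) <- "synthrig_sample"
  write_sample(ann, file.path(d2, "samples", "000000.json"))
  to_yolo(d2, file.path(tmp, "y"))
  line <- readLines(file.path(tmp, "y", "labels", "000000.txt"))
  expect_equal(line, "0 0.200000 0.300000 0.200000 0.200000")
})

test_that("uncompressed RLE encoding matches an independent decoder and pixel counts", {
  ds <- local_dataset()
  batch <- read_batch(file.path(ds, "batch.json"))
  coco_file <- withr::local_tempfile(fileext = ".json")
  coco <- to_coco(ds, coco_file, export_config(mask_encoding = "rle"))
  expect_true(length(coco$annotations) > 0)
  checked <- 0L
  for (a in coco$annotations) {
    m <- rle_to_mask(a$segmentation)
    expect_equal(sum(m), a$area)
    checked <- checked + 1L
  }
  expect_gte(checked, 1L)
  # per-image, annotation areas sum to the nonzero id-pass pixel total
  for (img in coco$images) {
    id_pass <- png::readPNG(file.path(ds, "passes", "id",
                                      sprintf("%06d.png", img$id)))
    nonzero <- sum(id_pass[, , 1] > 0 | id_pass[, , 2] > 0 | id_pass[, , 3] > 0)
    areas <- sum(vapply(Filter(function(a) a$image_id == img$id,
                               coco$annotations), `[[`, 0, "area"))
    expect_equal(areas, nonzero)
  }
  # decode independently in python (numpy) as a cross-check
  py <- Sys.which("python")
  if (nzchar(py)) {
    a <- coco$annotations[[1]]
    script <- sprintf(
      "import json,sys; d=json.load(open('%s'));a=d['annotations'][0];c=a['segmentation']['counts'];print(sum(c[1::2]))",
      coco_file)
    got <- as.integer(system2(py, c("-c", shQuote(script)), stdout = TRUE))
    expect_equal(got, a$area)
  }
})

test_that("COCO keypoint visibility codes and polygon masks are faithful", {
  ds <- local_dataset()
  coco_file <- withr::local_tempfile(fileext = ".json")
  coco <- to_coco(ds, coco_file, export_config(mask_encoding = "polygon"))
  vis_seen <- integer(0)
  for (a in coco$annotations) {
    kps <- matrix(a$keypoints, ncol = 3, byrow = TRUE)
    vis_seen <- union(vis_seen, kps[, 3])
    expect_true(all(kps[, 3] %in% c(0, 1, 2)))
    # v = 0 keypoints are zeroed
    expect_true(all(kps[kps[, 3] == 0, 1:2] == 0))
    # polygon area approximates the pixel count for solid shapes
    if (length(a$segmentation) > 0 && a$area > 50) {
      area_poly <- sum(vapply(a$segmentation, function(p) {
        m <- matrix(p, ncol = 2, byrow = TRUE)
        abs(sum(m[, 1] * c(m[-1, 2], m[1, 2]) - m[, 2] * c(m[-1, 1], m[1, 1]))) / 2
      }, 0))
      expect_lt(abs(area_poly - a$area) / a$area, 0.35)
    }
  }
  expect_true(2 %in% vis_seen)
  # visible keypoints map to v = 2 on a constructed case
  expect_equal(synthrig:::visibility_code("visible"), 2L)
  expect_equal(synthrig:::visibility_code("occluded"), 1L)
  expect_equal(synthrig:::visibility_code("out_of_frame"), 0L)
})

test_that("RLE and polygon encodings agree with a synthetic mask", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:12, 7:15] <- TRUE
  r <- mask_to_rle(mask)
  expect_equal(sum(r$counts), 400)
  expect_identical(rle_to_mask(r), mask)
  polys <- synthrig:::mask_to_polygons(mask, tol = 0)
  expect_equal(length(polys), 1)
  m <- polys[[1]]
  area <- abs(sum(m[, 1] * c(m[-1, 2], m[1, 2]) - m[, 2] * c(m[-1, 1], m[1, 1]))) / 2
  expect_equal(area, sum(mask))   # axis-aligned rectangle: exact
})

test_that("keypoint tables have the expected width and recover coordinates exactly", {
  ds <- local_dataset()
  out <- withr::local_tempdir()
  csv <- to_keypoint_table(ds, out, export_config())
  lines <- readLines(csv)
  first <- read_sample(dataset_samples(ds)[1])
  n_kp <- length(first$subjects[[1]]$keypoints)
  expect_equal(length(strsplit(lines[1], ",")[[1]]), 2 + 3 * n_kp)
  tab <- read_keypoint_table(csv)
  # visible coordinates recovered exactly
  smp <- read_sample(dataset_samples(ds)[1])
  for (s in smp$subjects) {
    for (k in s$keypoints) {
      if (k$visibility != "visible") next
      row <- tab[tab$image == sprintf("%06d", smp$sample_id) &
                   tab$instance == s$instance_id & tab$keypoint == k$name, ]
      if (nrow(row) == 0) next
      expect_equal(c(row$x, row$y), k$xy)
      expect_equal(row$likelihood, 1.0)
    }
  }
  # occlusion exclusion empties cells
  out2 <- withr::local_tempdir()
  csv2 <- to_keypoint_table(ds, out2, export_config(exclude_occluded = TRUE))
  tab2 <- read_keypoint_table(csv2)
  smp_all <- lapply(dataset_samples(ds), read_sample)
  occl <- NULL
  for (smp in smp_all) for (s in smp$subjects) for (k in s$keypoints) {
    if (k$visibility == "occluded" && !any(is.na(s$bbox)) && s$occupancy > 0) {
      occl <- list(img = sprintf("%06d", smp$sample_id), inst = s$instance_id,
                   kp = k$name)
    }
  }
  if (!is.null(occl)) {
    row <- tab2[tab2$image == occl$img & tab2$instance == occl$inst &
                  tab2$keypoint == occl$kp, ]
    expect_true(is.na(row$x))
  }
  # a model with 46 keypoints yields 138 coordinate/likelihood columns
  m46 <- make_stick_subject()
  extra <- 46 - length(m46$keypoints)
  for (i in seq_len(extra)) {
    m46$keypoints[[length(m46$keypoints) + 1]] <-
      list(name = sprintf("kp%02d", i), bone = "body",
           offset = c(i / 50, 0, 0.1))
  }
  expect_equal(3 * length(m46$keypoints), 138)
})

test_that("segmentation maps are binary or per-class and count subject pixels", {
  ds <- local_dataset()
  out <- withr::local_tempdir()
  paths <- to_segmentation_maps(ds, out)
  batch <- read_batch(file.path(ds, "batch.json"))
  for (p in paths) {
    lab <- read_segmentation_map(p)
    expect_true(all(lab %in% c(0L, 1L)))
    idx <- as.integer(sub("\\.png$", "", basename(p)))
    id_pass <- png::readPNG(file.path(ds, "passes", "id",
                                      sprintf("%06d.png", idx)))
    nonzero <- sum(id_pass[, , 1] > 0 | id_pass[, , 2] > 0 | id_pass[, , 3] > 0)
    expect_equal(sum(lab == 1L), nonzero)
  }
  # per-class mode uses labels 0..K
  out2 <- withr::local_tempdir()
  paths2 <- to_segmentation_maps(ds, out2, per_class = TRUE)
  lab2 <- read_segmentation_map(paths2[1])
  expect_true(all(lab2 %in% 0:length(unique(vapply(batch$subjects, `[[`, "", "class_name")))))
})

test_that("the 3D pose export is lossless and reprojects within half a pixel", {
  ds <- local_dataset()
  out_file <- withr::local_tempfile(fileext = ".json")
  to_pose3d(ds, out_file)
  p3d <- jsonlite::read_json(out_file, simplifyVector = FALSE)
  expect_equal(p3d$n_samples, length(dataset_samples(ds)))
  for (si in seq_along(p3d$samples)) {
    smp <- read_sample(dataset_samples(ds)[si])
    ex <- p3d$samples[[si]]
    K <- ex$intrinsics
    for (sj in seq_along(ex$subjects)) {
      orig <- smp$subjects[[sj]]
      for (kj in seq_along(ex$subjects[[sj]]$keypoints)) {
        k <- ex$subjects[[sj]]$keypoints[[kj]]
        xyz <- as.numeric(unlist(k$xyz_cam))
        expect_identical(xyz, orig$keypoints[[kj]]$xyz_cam)
        if (xyz[3] > 0) {
          u <- K$cx + K$fx * xyz[1] / xyz[3]
          v <- K$cy + K$fy * xyz[2] / xyz[3]
          expect_equal(c(u, v), as.numeric(unlist(k$xy)), tolerance = 0.5)
        }
      }
    }
  }
})

test_that("dataset splits are deterministic, disjoint and exhaustive", {
  s1 <- split_dataset(10000, 0.8, seed = 3)
  expect_length(s1$train, 8000)
  expect_length(s1$validation, 2000)
  expect_length(intersect(s1$train, s1$validation), 0)
  expect_setequal(c(s1$train, s1$validation), 0:9999)
  expect_identical(s1, split_dataset(10000, 0.8, seed = 3))
  expect_false(identical(s1$train, split_dataset(10000, 0.8, seed = 4)$train))
  expect_error(split_dataset(100, 1.0), "open interval")
})

test_that("exporters leave the dataset byte-identical", {
  ds <- local_dataset()
  files <- list.files(ds, recursive = TRUE, full.names = TRUE)
  before <- tools::md5sum(files)
  out <- withr::local_tempdir()
  to_yolo(ds, file.path(out, "y"))
  to_coco(ds, file.path(out, "c.json"), export_config(mask_encoding = "rle"))
  to_keypoint_table(ds, file.path(out, "k"))
  to_segmentation_maps(ds, file.path(out, "s"))
  to_pose3d(ds, file.path(out, "p.json"))
  expect_identical(tools::md5sum(files), before)
})
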