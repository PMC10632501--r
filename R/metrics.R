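# Evaluation statistics: centre-based average precision and its mean,
# multiple-object tracking accuracy with identity-switch bookkeeping and
# overlap-event suppression, relative pose error, and average class-wise
# recall — plus the seeded simulators used to exercise them.

#' Average-precision configuration
#'
#' @param thresholds descending confidence thresholds; default 13 equally
#'   spaced on `[0.2, 0.8]`.
#' @param center_tolerance_frac matching tolerance as a fraction of the
#'   image width (default 0.05).
#' @return an `synthrig_ap_config`.
#' @export
ap_config <- function(thresholds = seq(0.8, 0.2, length.out = 13),
                      center_tolerance_frac = 0.05) {
  if (is.unsorted(rev(thresholds), strictly = TRUE)) {
    stop("thresholds must be strictly descending")
  }
  structure(list(thresholds = thresholds,
                 center_tolerance_frac = center_tolerance_frac),
            class = "synthrig_ap_config")
}

# greedy matching at one threshold: each detection (descending confidence)
# claims its nearest unmatched ground-truth center within tolerance
match_detections <- function(det, gt, tol) {
  matched_gt <- logical(nrow(gt))
  tp <- 0L
  if (nrow(det) > 0) {
    for (i in order(-det$confidence, seq_len(nrow(det)))) {
      d <- sqrt((gt[, 1] - det$cx[i])^2 + (gt[, 2] - det$cy[i])^2)
      d[matched_gt] <- Inf
      j <- which.min(d)
      if (length(j) > 0 && d[j] <= tol) {
        matched_gt[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  list(tp = tp, fp = nrow(det) - tp)
}

#' Centre-based average precision
#'
#' A detection is correct when its center lies within 5% of the image width
#' of an unmatched ground-truth center. Sweeping the descending thresholds,
#' `AP = sum_n (R_n - R_{n-1}) P_n` with the seed `R_0 = 0`; at the maximal
#' threshold no detections are returned and the precision is unity by
#' definition (precision is likewise 1 whenever no detections survive a
#' threshold).
#'
#' @param detections data.frame `cx, cy, confidence` (optionally `frame`,
#'   matched per frame).
#' @param ground_truth matrix/data.frame of ground truth centers `cx, cy`
#'   (optionally `frame`).
#' @param image_width image width in px.
#' @param config an [ap_config()].
#' @return list `ap`, `precision`, `recall`, `thresholds`
#'   (class `synthrig_ap_result`).
#' @export
average_precision <- function(detections, ground_truth, image_width,
                              config = ap_config()) {
  gt <- as.data.frame(ground_truth)
  if (nrow(gt) == 0) stop("average_precision: empty ground truth")
  det <- as.data.frame(detections)
  tol <- config$center_tolerance_frac * image_width
  by_frame <- "frame" %in% names(gt) && "frame" %in% names(det)
  n_gt <- nrow(gt)
  P <- numeric(length(config$thresholds))
  R <- numeric(length(config$thresholds))
  for (k in seq_along(config$thresholds)) {
    thr <- config$thresholds[k]
    dk <- det[det$confidence >= thr, , drop = FALSE]
    if (by_frame) {
      tp <- 0L; fp <- 0L
      for (f in unique(gt$frame)) {
        mm <- match_detections(dk[dk$frame == f, , drop = FALSE],
                               as.matrix(gt[gt$frame == f, c("cx", "cy")]), tol)
        tp <- tp + mm$tp; fp <- fp + mm$fp
      }
      fp <- fp + sum(!dk$frame %in% gt$frame)
    } else {
      mm <- match_detections(dk, as.matrix(gt[, c("cx", "cy")]), tol)
      tp <- mm$tp; fp <- mm$fp
    }
    P[k] <- if (tp + fp == 0) 1 else tp / (tp + fp)
    R[k] <- tp / n_gt
  }
  ap <- sum((R - c(0, R[-length(R)])) * P)
  structure(list(ap = ap, precision = P, recall = R,
                 thresholds = config$thresholds),
            class = "synthrig_ap_result")
}

#' Mean average precision
#' @param aps numeric vector of per-case APs (or `synthrig_ap_result`s).
#' @return their arithmetic mean.
#' @export
mean_average_precision <- function(aps) {
  if (is.list(aps)) aps <- vapply(aps, function(a) a$ap %||% a, 0)
  mean(aps)
}

# --- MOTA --------------------------------------------------------------------

#' MOTA configuration
#' @param d_max maximum center distance (px) for a correct correspondence;
#'   default 50 px at 4k, i.e. 2% of the frame width.
#' @param frame_width when given and `d_max` is `NULL`, `d_max` is scaled
#'   as 2% of the frame width.
#' @return an `synthrig_mota_config`.
#' @export
mota_config <- function(d_max = 50, frame_width = NULL) {
  if (is.null(d_max)) {
    if (is.null(frame_width)) stop("need d_max or frame_width")
    d_max <- 0.02 * frame_width
  }
  if (d_max <= 0) stop("d_max must be > 0")
  structure(list(d_max = d_max), class = "synthrig_mota_config")
}

#' Multiple-object tracking accuracy
#'
#' Per frame, ground-truth and inferred tracks are matched by the Hungarian
#' method on center distances gated at `d_max`. Unmatched ground truth
#' counts as a false negative, unmatched inferred tracks as false
#' positives. An identity switch is counted when a ground-truth id's
#' matched inferred id differs from its stored correspondence; the new
#' identity is then considered correct for all subsequent frames. During
#' overlap events — maximal consecutive frame runs in which any two ground
#' truth tracks are closer than `d_max` — correspondence changes are not
#' counted or stored (transient swaps between crossing tracks are
#' suppressed) while FN/FP are still counted.
#' `MOTA = 1 - (FN + FP + IDS) / sum(gt detections)`.
#'
#' @param gt_tracks data.frame `frame, track_id, cx, cy`.
#' @param inferred_tracks data.frame `frame, track_id, cx, cy`.
#' @param config a [mota_config()].
#' @return list `mota, fn, fp, ids, total_gt, switches` (data.frame of
#'   id-switch events), class `synthrig_mota_result`.
#' @export
mota <- function(gt_tracks, inferred_tracks, config = mota_config()) {
  gt <- as.data.frame(gt_tracks)
  inf <- as.data.frame(inferred_tracks)
  if (nrow(gt) == 0) stop("mota: empty ground truth")
  frames <- sort(unique(gt$frame))
  if (nrow(inf) > 0 && (min(inf$frame) < min(frames) || max(inf$frame) > max(frames))) {
    stop("mota: inferred track frames outside the ground-truth frame range")
  }
  d_max <- config$d_max
  # overlap-event frames: any gt pair closer than d_max
  overlap_frame <- vapply(frames, function(f) {
    g <- gt[gt$frame == f, , drop = FALSE]
    if (nrow(g) < 2) return(FALSE)
    dm <- as.matrix(stats::dist(g[, c("cx", "cy")]))
    any(dm[upper.tri(dm)] < d_max)
  }, TRUE)
  corr <- new.env(parent = emptyenv())   # gt id -> inferred id
  fn <- 0L; fp <- 0L; ids <- 0L
  switches <- list()
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- inf[inf$frame == f, , drop = FALSE]
    asc <- associate(as.matrix(g[, c("cx", "cy")]),
                     as.matrix(h[, c("cx", "cy")]), d_max)
    fn <- fn + length(asc$unmatched_tracks)
    fp <- fp + length(asc$unmatched_detections)
    if (!overlap_frame[fi]) {
      if (nrow(asc$matches) > 0) {
        for (r in seq_len(nrow(asc$matches))) {
          gid <- as.character(g$track_id[asc$matches[r, 1]])
          hid <- h$track_id[asc$matches[r, 2]]
          prev <- corr[[gid]]
          if (!is.null(prev) && prev != hid) {
            ids <- ids + 1L
            switches[[length(switches) + 1L]] <- data.frame(
              frame = f, gt_id = as.integer(gid), old_id = prev, new_id = hid)
          }
          corr[[gid]] <- hid
        }
      }
    }
  }
  total <- nrow(gt)
  structure(list(mota = 1 - (fn + fp + ids) / total, fn = fn, fp = fp,
                 ids = ids, total_gt = total,
                 switches = if (length(switches)) do.call(rbind, switches) else
                   data.frame(frame = integer(0), gt_id = integer(0),
                              old_id = integer(0), new_id = integer(0))),
            class = "synthrig_mota_result")
}

# --- pose error --------------------------------------------------------------

#' Relative pose-estimation error
#'
#' The mean Euclidean pixel error over inferred keypoints with confidence
#' at or above the threshold (default 0.6), divided by the body length `l`
#' in pixels and expressed as a percentage. Also reports the retained
#' keypoint fraction (networks with half or fewer keypoints above threshold
#' are flagged by their low retained fraction).
#'
#' @param gt n x 2 matrix of ground-truth keypoint pixels.
#' @param inferred n x 2 matrix of inferred keypoint pixels.
#' @param confidences length-n confidences.
#' @param body_length body length `l` in px (> 0), e.g. the distance
#'   between the most distal head and abdomen points.
#' @param confidence_threshold retention threshold (default 0.6).
#' @return list `mean_px_error`, `relative_error_pct`, `n_retained`,
#'   `retained_fraction`, class `synthrig_pose_error`.
#' @export
pose_error <- function(gt, inferred, confidences, body_length,
                       confidence_threshold = 0.6) {
  if (body_length <= 0) stop("body_length must be > 0")
  gt <- matrix(gt, ncol = 2); inferred <- matrix(inferred, ncol = 2)
  keep <- confidences >= confidence_threshold
  if (!any(keep)) {
    stop("pose_error: undefined result - no keypoints at or above the ",
         "confidence threshold")
  }
  d <- sqrt(rowSums((gt[keep, , drop = FALSE] - inferred[keep, , drop = FALSE])^2))
  mean_px <- mean(d)
  structure(list(mean_px_error = mean_px,
                 relative_error_pct = 100 * mean_px / body_length,
                 body_length = body_length,
                 n_retained = sum(keep),
                 retained_fraction = mean(keep)),
            class = "synthrig_pose_error")
}

# --- ACR ---------------------------------------------------------------------

#' Average class-wise recall
#'
#' Per class and image: with `y` the ground-truth pixel count of the class,
#' `FP` the pixels falsely attributed to it and `FN` its pixels attributed
#' elsewhere, the per-image ratio is `(y - (FP + FN)) / y`. Ratios are
#' averaged over images, then over classes, and multiplied by 100.
#'
#' @param gt_maps integer label matrix or list of matrices.
#' @param pred_maps predicted label matrix/list with the same dimensions.
#' @param classes integer class labels to score (each must occur in the
#'   ground truth); defaults to all nonzero gt labels.
#' @return list `acr`, `per_class` (named vector of per-class percentages),
#'   class `synthrig_acr_result`.
#' @export
acr <- function(gt_maps, pred_maps, classes = NULL) {
  if (!is.list(gt_maps)) gt_maps <- list(gt_maps)
  if (!is.list(pred_maps)) pred_maps <- list(pred_maps)
  stopifnot(length(gt_maps) == length(pred_maps))
  all_gt <- unlist(lapply(gt_maps, function(m) unique(as.vector(m))))
  if (is.null(classes)) classes <- sort(setdiff(unique(all_gt), 0))
  if (length(classes) == 0) stop("acr: no classes to score")
  per_class <- vapply(classes, function(cl) {
    ratios <- vapply(seq_along(gt_maps), function(i) {
      g <- gt_maps[[i]]; p <- pred_maps[[i]]
      if (!all(dim(g) == dim(p))) stop("acr: map dimensions differ")
      y <- sum(g == cl)
      if (y == 0) return(NA_real_)
      fp <- sum(p == cl & g != cl)
      fn <- sum(g == cl & p != cl)
      (y - (fp + fn)) / y
    }, 0)
    if (all(is.na(ratios))) stop("acr: class ", cl, " absent from ground truth")
    mean(ratios, na.rm = TRUE)
  }, 0)
  names(per_class) <- as.character(classes)
  structure(list(acr = 100 * mean(per_class), per_class = 100 * per_class),
            class = "synthrig_acr_result")
}

# --- simulators --------------------------------------------------------------

#' Simulate a detector over ground-truth tracks
#'
#' Stands in for a trained detector: each ground-truth center is emitted
#' with probability `1 - fn_rate` and Gaussian center jitter; Poisson
#' clutter with mean `fp_rate` per frame is added uniformly over the image.
#' True detections draw confidence uniformly from `conf_tp`, clutter from
#' `conf_fp`.
#'
#' @param gt_tracks data.frame `frame, track_id, cx, cy` (as from
#'   [simulate_tracks()]).
#' @param image_dims `c(W, H)`.
#' @param fn_rate miss probability per ground-truth detection.
#' @param fp_rate expected clutter detections per frame.
#' @param jitter_sd center jitter standard deviation (px).
#' @param box_size emitted square box side (px).
#' @param conf_tp,conf_fp confidence ranges.
#' @param seed integer seed.
#' @return data.frame `frame, x_min, y_min, x_max, y_max, confidence, cx,
#'   cy`.
#' @export
simulate_detections <- function(gt_tracks, image_dims, fn_rate = 0, fp_rate = 0,
                                jitter_sd = 0, box_size = 40,
                                conf_tp = c(0.6, 1), conf_fp = c(0.2, 0.6),
                                seed = 1) {
  gt <- as.data.frame(gt_tracks)
  with_seed(seed, {
    keep <- stats::runif(nrow(gt)) >= fn_rate
    d <- gt[keep, , drop = FALSE]
    n <- nrow(d)
    cx <- d$cx + stats::rnorm(n, 0, jitter_sd)
    cy <- d$cy + stats::rnorm(n, 0, jitter_sd)
    conf <- stats::runif(n, conf_tp[1], conf_tp[2])
    out <- data.frame(frame = d$frame, cx = cx, cy = cy, confidence = conf)
    frames <- sort(unique(gt$frame))
    n_clutter <- stats::rpois(length(frames), fp_rate)
    if (sum(n_clutter) > 0) {
      cl <- data.frame(
        frame = rep(frames, n_clutter),
        cx = stats::runif(sum(n_clutter), 0, image_dims[1]),
        cy = stats::runif(sum(n_clutter), 0, image_dims[2]),
        confidence = stats::runif(sum(n_clutter), conf_fp[1], conf_fp[2]))
      out <- rbind(out, cl)
    }
    out <- out[order(out$frame), , drop = FALSE]
    out$x_min <- out$cx - box_size / 2
    out$x_max <- out$cx + box_size / 2
    out$y_min <- out$cy - box_size / 2
    out$y_max <- out$cy + box_size / 2
    rownames(out) <- NULL
    out[, c("frame", "x_min", "y_min", "x_max", "y_max", "confidence", "cx", "cy")]
  })
}

#' Simulate constant-velocity ground-truth tracks
#'
#' Targets move with constant velocity inside the image, reflecting at the
#' borders. With `crossing = FALSE` targets are laid out on well separated
#' horizontal lanes moving along x only, guaranteeing a minimum pairwise
#' separation; with `crossing = TRUE` directions are random and crossings
#' can occur.
#'
#' @param n_targets number of targets.
#' @param n_frames number of frames.
#' @param image_dims `c(W, H)`.
#' @param speed_range per-frame speed range (px).
#' @param crossing allow target paths to cross.
#' @param seed integer seed.
#' @return data.frame `frame, track_id, cx, cy`.
#' @export
simulate_tracks <- function(n_targets, n_frames, image_dims = c(2000, 2000),
                            speed_range = c(2, 6), crossing = FALSE, seed = 1) {
  W <- image_dims[1]; H <- image_dims[2]
  with_seed(seed, {
    if (crossing) {
      pos <- cbind(stats::runif(n_targets, 0.1 * W, 0.9 * W),
                   stats::runif(n_targets, 0.1 * H, 0.9 * H))
      ang <- stats::runif(n_targets, 0, 2 * pi)
      spd <- stats::runif(n_targets, speed_range[1], speed_range[2])
      vel <- cbind(cos(ang), sin(ang)) * spd
    } else {
      lanes <- H * (seq_len(n_targets)) / (n_targets + 1)
      pos <- cbind(stats::runif(n_targets, 0.1 * W, 0.9 * W), lanes)
      spd <- stats::runif(n_targets, speed_range[1], speed_range[2])
      vel <- cbind(spd * sample(c(-1, 1), n_targets, replace = TRUE), 0)
    }
    rows <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      rows[[f]] <- data.frame(frame = f - 1L, track_id = seq_len(n_targets),
                              cx = pos[, 1], cy = pos[, 2])
      pos <- pos + vel
      for (k in 1:2) {
        lim <- c(W, H)[k]
        over <- pos[, k] < 0 | pos[, k] > lim
        vel[over, k] <- -vel[over, k]
        pos[over, k] <- pmin(pmax(pos[over, k], 0), lim)
      }
    }
    do.call(rbind, rows)
  })
}
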