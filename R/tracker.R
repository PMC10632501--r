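# Detection-based buffer-and-recover multi-animal tracker.
#
# Per frame: detections are confidence- and size-filtered, duplicates
# removed by greedy NMS, all live tracks advanced by a constant-velocity
# Kalman prediction, predictions associated to detections by the Hungarian
# method on gated center distances, matched tracks updated, unmatched
# tracks coasted for up to `buffer` frames, and unmatched detections spawn
# new tracks with strictly increasing, never reused ids. The tracker is
# fully deterministic.

#' Tracker configuration
#'
#' @param confidence_threshold minimum detection confidence (default 0.5).
#' @param nms_threshold IoU above which the lower-confidence duplicate is
#'   suppressed (default 0.45).
#' @param min_box_size minimum smaller box side in px (default 20; boxes
#'   smaller than this are excluded from association).
#' @param gate maximum center distance (px) for association.
#' @param buffer frames a track may coast without a detection before
#'   termination.
#' @param process_noise,measurement_noise Kalman noise scales.
#' @param cost `"center"` (Euclidean center distance) or `"iou"`
#'   (1 - IoU) association cost.
#' @return a `synthrig_tracker_config`.
#' @export
tracker_config <- function(confidence_threshold = 0.5, nms_threshold = 0.45,
                           min_box_size = 20, gate = 100, buffer = 30,
                           process_noise = 1e-2, measurement_noise = 1,
                           cost = "center") {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            nms_threshold >= 0, nms_threshold <= 1, gate > 0, buffer > 0)
  structure(list(confidence_threshold = confidence_threshold,
                 nms_threshold = nms_threshold, min_box_size = min_box_size,
                 gate = gate, buffer = buffer, process_noise = process_noise,
                 measurement_noise = measurement_noise, cost = cost),
            class = "synthrig_tracker_config")
}

box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) 0 else inter / union
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in descending confidence (ties broken by lower index);
#' a box is suppressed when its IoU with an already kept box exceeds the
#' threshold.
#'
#' @param detections data.frame with `x_min`, `y_min`, `x_max`, `y_max`,
#'   `confidence`.
#' @param overlap_threshold IoU threshold.
#' @return the kept subset, original order preserved.
#' @export
nms <- function(detections, overlap_threshold = 0.45) {
  n <- nrow(detections)
  if (n == 0) return(detections)
  ord <- order(-detections$confidence, seq_len(n))
  keep <- logical(n)
  boxes <- as.matrix(detections[, c("x_min", "y_min", "x_max", "y_max")])
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (box_iou(boxes[i, ], boxes[j, ]) > overlap_threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  detections[keep, , drop = FALSE]
}

#' Confidence and size filtering of detections
#'
#' Drops detections below the confidence threshold and boxes whose smaller
#' side is below the minimum size (boundary inclusive: a box exactly at the
#' minimum is kept).
#'
#' @param detections data.frame as in [nms()].
#' @param config a [tracker_config()].
#' @return the filtered subset.
#' @export
filter_detections <- function(detections, config = tracker_config()) {
  if (nrow(detections) == 0) return(detections)
  side <- pmin(detections$x_max - detections$x_min,
               detections$y_max - detections$y_min)
  detections[detections$confidence >= config$confidence_threshold &
               side >= config$min_box_size, , drop = FALSE]
}

# --- Kalman filter (constant velocity, dt = 1) -------------------------------

kalman_matrices <- function(config) {
  FT <- diag(4); FT[1, 3] <- 1; FT[2, 4] <- 1
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  # process noise on the velocity components (discrete white acceleration)
  Q <- diag(c(0.25, 0.25, 1, 1)) * config$process_noise
  R <- diag(2) * config$measurement_noise
  list(F = FT, H = H, Q = Q, R = R)
}

#' Initialize a Kalman state from a first measurement
#' @param center length-2 measured center.
#' @param config a [tracker_config()].
#' @return list `x` (state `cx, cy, vx, vy`), `P` (covariance).
#' @export
kalman_init <- function(center, config = tracker_config()) {
  list(x = c(center, 0, 0),
       P = diag(c(config$measurement_noise, config$measurement_noise, 1e12, 1e12)))
}

#' Kalman predict step
#' @param state list `x`, `P`.
#' @param config a [tracker_config()].
#' @return the predicted state.
#' @export
kalman_predict <- function(state, config = tracker_config()) {
  m <- kalman_matrices(config)
  x <- as.numeric(m$F %*% state$x)
  P <- m$F %*% state$P %*% t(m$F) + m$Q
  list(x = x, P = (P + t(P)) / 2)
}

#' Kalman update step
#' @param state predicted state.
#' @param measurement length-2 measured center.
#' @param config a [tracker_config()].
#' @return the posterior state.
#' @export
kalman_update <- function(state, measurement, config = tracker_config()) {
  m <- kalman_matrices(config)
  y <- measurement - as.numeric(m$H %*% state$x)
  S <- m$H %*% state$P %*% t(m$H) + m$R
  K <- state$P %*% t(m$H) %*% solve(S)
  x <- as.numeric(state$x + K %*% y)
  IKH <- diag(4) - K %*% m$H
  # Joseph form keeps the covariance symmetric PSD
  P <- IKH %*% state$P %*% t(IKH) + K %*% m$R %*% t(K)
  list(x = x, P = (P + t(P)) / 2)
}

# --- Hungarian assignment ----------------------------------------------------

#' Minimum-cost bipartite assignment (Hungarian / shortest augmenting path)
#'
#' Solves the rectangular linear assignment problem exactly.
#'
#' @param cost n x m cost matrix (finite entries; use a large cost, not
#'   `Inf`, for forbidden pairs).
#' @return integer vector of length `n`: `a[i]` = assigned column of row i,
#'   or `NA` when rows exceed columns and row i is unassigned.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  # Jonker-Volgenant style shortest augmenting path, rows <= cols
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j] = row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1) break
    }
  }
  ans <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0) ans[p[j]] <- j
  if (transposed) {
    full <- rep(NA_integer_, m)
    for (i in seq_len(n)) if (!is.na(ans[i])) full[ans[i]] <- i
    full
  } else ans
}

#' Associate predicted track centers with detections
#'
#' Minimum-total-cost one-to-one assignment (Hungarian method) on Euclidean
#' center distances; pairs beyond the gate are forbidden.
#'
#' @param predicted n x 2 matrix of predicted track centers.
#' @param detected m x 2 matrix of detection centers.
#' @param gate maximum admissible distance (px).
#' @return list `matches` (k x 2 matrix of (track, detection) indices),
#'   `unmatched_tracks`, `unmatched_detections`.
#' @export
associate <- function(predicted, detected, gate) {
  n <- nrow(predicted); m <- nrow(detected)
  if (n == 0 || m == 0) {
    return(list(matches = matrix(0L, 0, 2), unmatched_tracks = seq_len(n),
                unmatched_detections = seq_len(m)))
  }
  d <- sqrt(outer(predicted[, 1], detected[, 1], "-")^2 +
              outer(predicted[, 2], detected[, 2], "-")^2)
  big <- max(gate, max(d[is.finite(d)])) * 1e3 + 1
  cost <- ifelse(d <= gate, d, big)
  a <- solve_assignment(cost)
  matches <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    if (!is.na(a[i]) && d[i, a[i]] <= gate) {
      matches <- rbind(matches, c(i, a[i]))
    }
  }
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n), matches[, 1]),
       unmatched_detections = setdiff(seq_len(m), matches[, 2]))
}

# --- lifecycle ---------------------------------------------------------------

new_tracker_state <- function(config = tracker_config()) {
  list(config = config, tracks = list(), next_id = 1L, frame = NA_integer_,
       rows = list())
}

det_centers <- function(d) {
  cbind((d$x_min + d$x_max) / 2, (d$y_min + d$y_max) / 2)
}

#' Advance the tracker by one frame of detections
#'
#' filter -> NMS -> predict -> associate -> update; unmatched tracks coast
#' (terminated once `frames_since_detection` exceeds the buffer), unmatched
#' detections spawn new tracks.
#'
#' @param state tracker state from `new_tracker_state()` or a previous
#'   `step_tracker()`.
#' @param detections data.frame `frame, x_min, y_min, x_max, y_max,
#'   confidence` (single frame).
#' @param frame frame index.
#' @return the updated state (rows of the output table accumulate in
#'   `state$rows`).
#' @export
step_tracker <- function(state, detections, frame) {
  cfg <- state$config
  d <- filter_detections(detections, cfg)
  d <- nms(d, cfg$nms_threshold)
  live <- which(vapply(state$tracks, function(t) t$status != "terminated", TRUE))
  for (i in live) {
    state$tracks[[i]]$kf <- kalman_predict(state$tracks[[i]]$kf, cfg)
  }
  predicted <- if (length(live)) {
    t(vapply(state$tracks[live], function(t) t$kf$x[1:2], numeric(2)))
  } else matrix(0, 0, 2)
  centers <- det_centers(d)
  asc <- associate(predicted, centers, cfg$gate)
  matched_tracks <- integer(0)
  if (nrow(asc$matches) > 0) {
    for (r in seq_len(nrow(asc$matches))) {
      ti <- live[asc$matches[r, 1]]; di <- asc$matches[r, 2]
      state$tracks[[ti]]$kf <- kalman_update(state$tracks[[ti]]$kf, centers[di, ], cfg)
      state$tracks[[ti]]$status <- "active"
      state$tracks[[ti]]$frames_since_detection <- 0L
      state$tracks[[ti]]$box <- as.numeric(d[di, c("x_min", "y_min", "x_max", "y_max")])
      matched_tracks <- c(matched_tracks, ti)
    }
  }
  for (i in setdiff(live, matched_tracks)) {
    fsd <- state$tracks[[i]]$frames_since_detection + 1L
    state$tracks[[i]]$frames_since_detection <- fsd
    state$tracks[[i]]$status <- if (fsd > cfg$buffer) "terminated" else "lost"
  }
  for (di in asc$unmatched_detections) {
    state$tracks[[length(state$tracks) + 1L]] <- list(
      id = state$next_id, kf = kalman_init(centers[di, ], cfg),
      status = "active", frames_since_detection = 0L,
      box = as.numeric(d[di, c("x_min", "y_min", "x_max", "y_max")]))
    state$next_id <- state$next_id + 1L
  }
  for (t in state$tracks) {
    if (t$status == "terminated") next
    # coasting tracks report their Kalman-predicted position so identities
    # bridge detection gaps (the "buffer" in buffer-and-recover); the last
    # box is re-centered on the prediction
    w <- (t$box[3] - t$box[1]) / 2; h <- (t$box[4] - t$box[2]) / 2
    state$rows[[length(state$rows) + 1L]] <- data.frame(
      frame = frame, track_id = t$id, cx = t$kf$x[1], cy = t$kf$x[2],
      x_min = t$kf$x[1] - w, y_min = t$kf$x[2] - h,
      x_max = t$kf$x[1] + w, y_max = t$kf$x[2] + h)
  }
  state$frame <- frame
  state
}

#' Track a full detection stream
#'
#' Folds [step_tracker()] over the frames of a detection table and returns
#' the per-frame track table.
#'
#' @param detections data.frame `frame, x_min, y_min, x_max, y_max,
#'   confidence` covering all frames; frames without rows are processed as
#'   empty.
#' @param config a [tracker_config()].
#' @param frames optional frame range (defaults to `min:max` of the data).
#' @return data.frame `frame, track_id, cx, cy, x_min, y_min, x_max, y_max`.
#' @export
track_sequence <- function(detections, config = tracker_config(), frames = NULL) {
  empty <- data.frame(frame = integer(0), track_id = integer(0),
                      cx = numeric(0), cy = numeric(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0), y_max = numeric(0))
  if (nrow(detections) == 0 && is.null(frames)) return(empty)
  if (is.null(frames)) frames <- seq(min(detections$frame), max(detections$frame))
  state <- new_tracker_state(config)
  for (f in frames) {
    state <- step_tracker(state, detections[detections$frame == f, , drop = FALSE], f)
  }
  if (length(state$rows) == 0) return(empty)
  out <- do.call(rbind, state$rows)
  rownames(out) <- NULL
  out
}
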