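# brute-force AP oracle: enumerate matching at every threshold directly
ap_oracle <- function(det, gt, width, thresholds = seq(0.8, 0.2, length.out = 13),
                      tol_frac = 0.05) {
  tol <- tol_frac * width
  P <- numeric(length(thresholds)); R <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    d <- det[det$confidence >= thresholds[k], , drop = FALSE]
    used <- logical(nrow(gt))
    tp <- 0L
    for (i in order(-d$confidence, seq_len(nrow(d)))) {
      dd <- sqrt((gt$cx - d$cx[i])^2 + (gt$cy - d$cy[i])^2)
      dd[used] <- Inf
      j <- which.min(dd)
      if (length(j) && dd[j] <= tol) { used[j] <- TRUE; tp <- tp + 1L }
    }
    P[k] <- if (nrow(d) == 0) 1 else tp / nrow(d)
    R[k] <- tp / nrow(gt)
  }
  sum((R - c(0, R[-length(R)])) * P)
}

test_that("AP attains its definitional seed values and endpoints", {
  gt <- data.frame(cx = c(10, 50, 90), cy = c(10, 50, 90))
  perfect <- data.frame(cx = gt$cx, cy = gt$cy, confidence = 0.9)
  res <- average_precision(perfect, gt, image_width = 100)
  expect_equal(res$ap, 1.0)
  # seed point: precision 1 at the maximal threshold bracket, recall seeded 0
  expect_equal(res$precision[1], 1.0)
  none <- data.frame(cx = numeric(0), cy = numeric(0), confidence = numeric(0))
  expect_equal(average_precision(none, gt, 100)$ap, 0.0)
  expect_true(all(average_precision(none, gt, 100)$precision == 1))
  expect_true(all(average_precision(none, gt, 100)$recall == 0))
  expect_error(average_precision(perfect, gt[0, ], 100), "empty ground truth")
})

test_that("AP matches the hand-enumerated sweep on the constructed TP/FP case", {
  gt <- data.frame(cx = c(20, 80), cy = c(50, 50))
  det <- data.frame(cx = c(20, 50, 80), cy = c(50, 10, 50),
                    confidence = c(0.7, 0.7, 0.3))
  # detection 2 is far from any gt (FP); tolerance 5 px at width 100
  res <- average_precision(det, gt, 100)
  expect_equal(res$ap, ap_oracle(det, gt, 100))
  # hand check: thresholds > 0.7 -> no det, P = 1, R = 0; 0.35..0.7 -> 1 TP
  # 1 FP, P = 0.5, R = 0.5; <= 0.3 -> 2 TP 1 FP, P = 2/3, R = 1
  expect_equal(res$ap, 0.5 * 0.5 + 0.5 * 2 / 3)
})

test_that("AP equals the brute-force oracle on 100 random instances", {
  set.seed(99)
  for (rep in 1:100) {
    n_gt <- sample(1:10, 1)
    n_det <- sample(0:20, 1)
    gt <- data.frame(cx = runif(n_gt, 0, 100), cy = runif(n_gt, 0, 100))
    det <- data.frame(cx = runif(n_det, 0, 100), cy = runif(n_det, 0, 100),
                      confidence = round(runif(n_det), 3))
    res <- average_precision(det, gt, 100)
    expect_equal(res$ap, ap_oracle(det, gt, 100), tolerance = 1e-12)
  }
})

test_that("AP is order-invariant and non-decreasing when an FP drops below all thresholds", {
  set.seed(7)
  gt <- data.frame(cx = runif(5, 0, 100), cy = runif(5, 0, 100))
  det <- data.frame(cx = c(gt$cx + 1, 70), cy = c(gt$cy, 95),
                    confidence = c(runif(5, 0.5, 1), 0.6))
  a1 <- average_precision(det, gt, 100)$ap
  a2 <- average_precision(det[sample(nrow(det)), ], gt, 100)$ap
  expect_equal(a1, a2)
  det_low <- det
  det_low$confidence[6] <- 0.1  # below all thresholds
  expect_gte(average_precision(det_low, gt, 100)$ap, a1)
})

test_that("mAP is the arithmetic mean of per-case APs", {
  expect_equal(mean_average_precision(c(1, 0)), 0.5)
  expect_equal(mean_average_precision(0.73), 0.73)
  expect_equal(mean_average_precision(c(0.2, 0.4, 0.9)), 0.5)
})

test_that("MOTA is unity on self-comparison and counts a single miss as 1 - 1/N", {
  gt <- simulate_tracks(5, 20, image_dims = c(1000, 1000), seed = 3)
  self <- data.frame(frame = gt$frame, track_id = gt$track_id + 100,
                     cx = gt$cx, cy = gt$cy)
  res <- mota(gt, self, mota_config(d_max = 20))
  expect_equal(res$mota, 1.0)
  expect_equal(res$fn + res$fp + res$ids, 0)
  # 100 gt detections with exactly one missed
  gt2 <- simulate_tracks(5, 20, image_dims = c(1000, 1000), seed = 4)
  stopifnot(nrow(gt2) == 100)
  inf2 <- gt2[-37, ]
  res2 <- mota(gt2, inf2, mota_config(d_max = 20))
  expect_equal(res2$fn, 1)
  expect_equal(res2$fp, 0)
  expect_equal(res2$ids, 0)
  expect_equal(res2$mota, 0.99)
  # accounting identity
  expect_equal(res2$fn + res2$fp + res2$ids,
               res2$total_gt * (1 - res2$mota), tolerance = 1e-12)
})

test_that("MOTA counts extra inferred tracks as false positives", {
  gt <- simulate_tracks(3, 10, image_dims = c(1000, 1000), seed = 5)
  clutter <- data.frame(frame = 0:9, track_id = 99,
                        cx = 990, cy = 990)
  inf <- rbind(data.frame(frame = gt$frame, track_id = gt$track_id,
                          cx = gt$cx, cy = gt$cy), clutter)
  res <- mota(gt, inf, mota_config(d_max = 20))
  expect_equal(res$fp, 10)
  expect_equal(res$mota, 1 - 10 / nrow(gt))
})

# two targets on straight crossing paths; constructed so they come within
# d_max during a known frame window
crossing_pair <- function(n_frames = 20, d_max = 50) {
  f <- 0:(n_frames - 1)
  y1 <- 100 + 20 * f; y2 <- 480 - 20 * f
  rbind(data.frame(frame = f, track_id = 1, cx = 300, cy = y1),
        data.frame(frame = f, track_id = 2, cx = 300, cy = y2))
}

test_that("MOTA identity-switch bookkeeping matches hand counts around crossings", {
  d_max <- 50
  gt <- crossing_pair(20, d_max)
  # the tracks meet at frame ~9.5; overlap frames are those with |y1-y2| < 50
  sep <- abs((100 + 20 * 0:19) - (480 - 20 * 0:19))
  overlap <- which(sep < d_max) - 1L
  expect_true(length(overlap) >= 1)
  # case 1: inferred follows gt exactly but swaps labels inside the overlap
  # window only -> transient swap, IDS = 0
  inf <- gt
  inf$track_id <- inf$track_id + 10
  swap <- inf$frame %in% overlap
  inf$track_id[swap] <- ifelse(inf$track_id[swap] == 11, 12, 11)
  res <- mota(gt, inf, mota_config(d_max = d_max))
  expect_equal(res$ids, 0)
  expect_equal(res$mota, 1.0)
  # case 2: permanent swap after the crossing -> one switch per reassigned id
  inf2 <- gt
  inf2$track_id <- inf2$track_id + 10
  after <- inf2$frame > max(overlap)
  inf2$track_id[after] <- ifelse(inf2$track_id[after] == 11, 12, 11)
  res2 <- mota(gt, inf2, mota_config(d_max = d_max))
  expect_equal(res2$ids, 2)
  expect_equal(nrow(res2$switches), 2)
  # the new identities count as correct afterwards: no further switches
  expect_true(all(res2$switches$frame == min(res2$switches$frame)))
})

test_that("pose error implements the relative formula and the retention threshold", {
  gt <- matrix(runif(20, 0, 100), ncol = 2)
  expect_equal(pose_error(gt, gt, rep(1, 10), body_length = 100)$relative_error_pct, 0)
  # uniform 5 px offset with l = 100 gives exactly 5%
  off <- gt + matrix(rep(c(3, 4), each = 10), ncol = 2)
  res <- pose_error(gt, off, rep(0.9, 10), body_length = 100)
  expect_equal(res$mean_px_error, 5)
  expect_equal(res$relative_error_pct, 5.0)
  expect_equal(res$retained_fraction, 1)
  # translation invariance and linear scaling in the offset
  res2 <- pose_error(gt + 50, off + 50, rep(0.9, 10), body_length = 100)
  expect_equal(res2$relative_error_pct, res$relative_error_pct)
  off2 <- gt + matrix(rep(c(6, 8), each = 10), ncol = 2)
  expect_equal(pose_error(gt, off2, rep(0.9, 10), 100)$relative_error_pct, 10.0)
  # all confidences below the threshold: undefined, not silently zero
  expect_error(pose_error(gt, off, rep(0.5, 10), 100, confidence_threshold = 0.6),
               "undefined")
  # keypoints below the threshold are excluded from the mean
  conf <- c(rep(0.9, 5), rep(0.1, 5))
  mixed <- gt
  mixed[6:10, ] <- mixed[6:10, ] + 1000
  res3 <- pose_error(gt, mixed, conf, 100)
  expect_equal(res3$mean_px_error, 0)
  expect_equal(res3$retained_fraction, 0.5)
})

test_that("ACR reproduces the closed-form class-wise recall", {
  gt <- matrix(0L, 20, 20)
  gt[1:10, 1:20] <- 1L           # 200 subject pixels
  pred <- gt
  expect_equal(acr(gt, pred)$acr, 100)
  # FN = 20 (misses), FP = 10 (spurious)
  pred2 <- gt
  pred2[1, 1:20] <- 0L           # 20 false negatives
  pred2[11, 1:10] <- 1L          # 10 false positives
  expect_equal(acr(gt, pred2)$acr, 85.0)
  # all-background prediction scores 0
  expect_equal(acr(gt, matrix(0L, 20, 20))$acr, 0)
  # dimension and class guards
  expect_error(acr(gt, matrix(0L, 10, 10)), "dimensions")
  expect_error(acr(gt, pred, classes = 2), "absent")
  # multi-image averaging: mean over images then classes
  res <- acr(list(gt, gt), list(pred, pred2))
  expect_equal(res$acr, (100 + 85) / 2)
})

test_that("the detection simulator honors its rates and determinism", {
  gt <- simulate_tracks(10, 100, image_dims = c(2000, 2000), seed = 6)
  d1 <- simulate_detections(gt, c(2000, 2000), fn_rate = 0.1, fp_rate = 0.5,
                            jitter_sd = 2, seed = 9)
  d2 <- simulate_detections(gt, c(2000, 2000), fn_rate = 0.1, fp_rate = 0.5,
                            jitter_sd = 2, seed = 9)
  expect_identical(d1, d2)
  # emitted fraction within 3 binomial sigmas of 1 - fn
  n_gt <- nrow(gt)
  n_tp <- sum(d1$confidence >= 0.6)   # tp confidences are >= 0.6 by the model
  phat <- n_tp / n_gt
  expect_lt(abs(phat - 0.9), 3 * sqrt(0.9 * 0.1 / n_gt))
  # zero-noise simulation scores a perfect AP against its own ground truth
  d0 <- simulate_detections(gt, c(2000, 2000), seed = 1)
  ap <- average_precision(
    data.frame(frame = d0$frame, cx = d0$cx, cy = d0$cy,
               confidence = d0$confidence),
    data.frame(frame = gt$frame, cx = gt$cx, cy = gt$cy), 2000)
  expect_equal(ap$ap, 1.0)
})

test_that("the track simulator produces the promised geometry", {
  gt <- simulate_tracks(10, 200, image_dims = c(2000, 2000), seed = 2)
  expect_equal(nrow(gt), 2000)
  expect_identical(gt, simulate_tracks(10, 200, image_dims = c(2000, 2000), seed = 2))
  # non-crossing lanes stay beyond d_max: no overlap events, self-MOTA exact
  res <- mota(gt, transform(gt, track_id = track_id + 50), mota_config(d_max = 50))
  expect_equal(res$mota, 1.0)
  sep_min <- min(vapply(split(gt, gt$frame), function(g) {
    min(dist(cbind(g$cx, g$cy)))
  }, 0))
  expect_gt(sep_min, 50)
})

test_that("noisy detections tracked end-to-end still recover all identities", {
  gt <- simulate_tracks(10, 200, image_dims = c(2000, 2000), seed = 12)
  det <- simulate_detections(gt, c(2000, 2000), fn_rate = 0.05, fp_rate = 0,
                             jitter_sd = 1.5, box_size = 40, seed = 12)
  tracks <- track_sequence(filter_detections(det, tracker_config()),
                           tracker_config(gate = 100, buffer = 30),
                           frames = 0:199)
  res <- mota(gt, tracks, mota_config(d_max = 50))
  expect_gte(res$mota, 0.95)
  expect_equal(res$ids, 0)
})
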