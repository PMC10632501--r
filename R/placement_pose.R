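# Subject placement (rejection sampling + down-vector trace) and posing
# (ray-cast foot targets, joint-limited cyclic-coordinate-descent IK, and
# randomized mesh-independent joints).

# --- world proxies -----------------------------------------------------------

# Per-bone world collision spheres for an instance at a given pose/placement.
# placement: list(position, rotation (euler deg)); pose: named angle list.
subject_world_proxies <- function(instance, placement, pose = NULL) {
  model <- instance$model
  if (is.null(pose)) pose <- zero_pose(model)
  fr <- bone_frames(model, pose, instance$scale)
  Rc <- euler_to_matrix(placement$rotation)
  ctr <- subject_center_rest(instance)
  lapply(model$proxies, function(pr) {
    i <- pr$bone
    local <- fr$t[i, ] + as.numeric(fr$R[[i]] %*% (pr$center * instance$scale))
    world <- placement$position + as.numeric(Rc %*% (local - ctr))
    list(center = world, radius = pr$radius * instance$scale)
  })
}

# geometric center of the rest mesh, scaled; placements position this point
subject_center_rest <- function(instance) {
  v <- instance$model$mesh$vertices
  ctr <- (apply(v, 2, min) + apply(v, 2, max)) / 2
  ctr * instance$scale
}

proxies_intersect_scene <- function(proxies, scene, skip_subject = 0L) {
  for (p in proxies) {
    h <- terrain_height(scene$terrain, p$center[1], p$center[2])
    if (!is.na(h) && p$center[3] - p$radius < h - 1e-9) return(TRUE)
    for (a in scene$assets) {
      if (sphere_aabb_overlap(p$center, p$radius, a$aabb$lo, a$aabb$hi)) return(TRUE)
    }
    for (si in seq_along(scene$subjects)) {
      if (si == skip_subject) next
      for (q in scene$subjects[[si]]$proxies) {
        if (vnorm(p$center - q$center) < p$radius + q$radius) return(TRUE)
      }
    }
  }
  FALSE
}

# first contact distance when sweeping a sphere along unit direction `dir`
sweep_sphere <- function(center, radius, dir, scene, skip_subject = 0L, max_t = Inf) {
  best <- Inf
  # terrain: clearance root along the swept path, marching + bisection
  f <- function(t) {
    p <- center + t * dir
    h <- terrain_height(scene$terrain, p[1], p[2])
    if (is.na(h)) return(NA_real_)
    p[3] - radius - h
  }
  t_max <- min(max_t, (center[3] + scene$terrain$amplitude + radius + 2) /
                 max(-dir[3], 1e-6))
  if (is.finite(t_max) && t_max > 0) {
    step <- max(t_max / 200, 1e-4)
    t0 <- 0; f0 <- f(0)
    t <- step
    while (t <= t_max + step && !is.na(f0)) {
      f1 <- f(t)
      if (is.na(f1)) break
      if (f0 > 0 && f1 <= 0) {          # bracketed: bisect
        lo <- t0; hi <- t
        for (k in 1:60) {
          mid <- (lo + hi) / 2
          if (f(mid) > 0) lo <- mid else hi <- mid
        }
        best <- min(best, hi)
        break
      }
      t0 <- t; f0 <- f1; t <- t + step
    }
  }
  for (a in scene$assets) {
    t <- ray_aabb(center, dir, a$aabb$lo - radius, a$aabb$hi + radius)
    if (t < best) best <- t
  }
  for (si in seq_along(scene$subjects)) {
    if (si == skip_subject) next
    for (q in scene$subjects[[si]]$proxies) {
      t <- ray_sphere(center, dir, q$center, radius + q$radius)
      if (t < best) best <- t
    }
  }
  best
}

#' Place a subject in the scene
#'
#' A candidate position above the terrain and a random center rotation are
#' drawn; candidates that start below ground or whose collision proxies
#' intersect the terrain, a scattered asset or a previously placed subject
#' are rejected and redrawn. The accepted candidate is then translated along
#' its down-vector (world -Z rotated by the center rotation) until first
#' proxy contact; if the trace leaves the world without contact, a new
#' rotation is drawn and the trace repeated.
#'
#' @param scene scene list with `terrain`, `assets`, `subjects`.
#' @param instance a `synthrig_instance`.
#' @param seed integer seed.
#' @param retry_cap maximum number of attempts (>= 1).
#' @param config list: `start_height` range above the local surface,
#'   `tilt_range` (+/- degrees for pitch/roll; yaw is always full circle).
#' @return list `position`, `rotation`, `attempts_used` (class
#'   `synthrig_placement`).
#' @export
place_subject <- function(scene, instance, seed, retry_cap = 100,
                          config = list(start_height = c(1, 3), tilt_range = 25)) {
  if (retry_cap < 1) stop("retry_cap must be >= 1")
  half <- scene$terrain$extent / 2 * 0.9
  ext <- max(apply(instance$model$mesh$vertices, 2, function(x) diff(range(x)))) *
    instance$scale
  with_seed(seed, {
    attempts <- 0L
    while (attempts < retry_cap) {
      attempts <- attempts + 1L
      x <- stats::runif(1, -half, half)
      y <- stats::runif(1, -half, half)
      h <- terrain_height(scene$terrain, x, y)
      z <- h + runif1(config$start_height) * ext
      rot <- c(stats::runif(1, -config$tilt_range, config$tilt_range),
               stats::runif(1, -config$tilt_range, config$tilt_range),
               stats::runif(1, 0, 360))
      if (z < h) next                    # below-ground start: rejected
      placement <- list(position = c(x, y, z), rotation = rot)
      proxies <- subject_world_proxies(instance, placement)
      if (proxies_intersect_scene(proxies, scene)) next
      dirv <- as.numeric(euler_to_matrix(rot) %*% c(0, 0, -1))
      t_hit <- min(vapply(proxies, function(p) {
        sweep_sphere(p$center, p$radius, dirv, scene)
      }, 0))
      if (!is.finite(t_hit)) next        # trace exits the world: new rotation
      placement$position <- placement$position + t_hit * dirv
      placement$attempts_used <- attempts
      class(placement) <- "synthrig_placement"
      return(placement)
    }
    stop(sprintf("placement error: retry cap exhausted after %d attempts", attempts))
  })
}

#' Ray-cast a candidate foot target
#'
#' Casts a downward ray from a jittered point above the foot's rest
#' location and returns the first surface hit on the terrain, scattered
#' assets or other subjects' proxies, or `NULL` when the ray exits the
#' world.
#'
#' @param foot_rest length-3 world position of the foot in the placed rest
#'   pose.
#' @param scene scene list.
#' @param seed integer seed.
#' @param jitter horizontal jitter radius (world units).
#' @param skip_subject index of the subject being posed (its own proxies are
#'   ignored).
#' @return length-3 hit point or `NULL`.
#' @export
ray_cast_foot_target <- function(foot_rest, scene, seed, jitter = 0.2,
                                 skip_subject = 0L) {
  with_seed(seed, {
    ox <- foot_rest[1] + stats::runif(1, -jitter, jitter)
    oy <- foot_rest[2] + stats::runif(1, -jitter, jitter)
  })
  origin <- c(ox, oy, foot_rest[3] + 2 * jitter + 1)
  dir <- c(0, 0, -1)
  best <- Inf
  h <- terrain_height(scene$terrain, ox, oy)
  if (!is.na(h)) best <- origin[3] - h
  for (a in scene$assets) {
    t <- ray_aabb(origin, dir, a$aabb$lo, a$aabb$hi)
    if (t < best) best <- t
  }
  for (si in seq_along(scene$subjects)) {
    if (si == skip_subject) next
    for (q in scene$subjects[[si]]$proxies) {
      t <- ray_sphere(origin, dir, q$center, q$radius)
      if (t < best) best <- t
    }
  }
  if (!is.finite(best)) return(NULL)
  origin + best * dir
}

# --- inverse kinematics ------------------------------------------------------

# world-frame FK for one subject: bone frames composed with the placement
subject_world_frames <- function(instance, placement, pose) {
  fr <- bone_frames(instance$model, pose, instance$scale)
  Rc <- euler_to_matrix(placement$rotation)
  ctr <- subject_center_rest(instance)
  n <- length(fr$R)
  list(R = lapply(fr$R, function(R) Rc %*% R),
       t = t(vapply(seq_len(n), function(i) {
         placement$position + as.numeric(Rc %*% (fr$t[i, ] - ctr))
       }, numeric(3))))
}

ancestors_path <- function(model, i) {
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- model$parent_idx[i]
  }
  path
}

# FK restricted to the root->bone path of one chain tip; used inside the
# IK inner loop where recomputing all bones would dominate the run time
chain_world_frames <- function(instance, placement, pose, path) {
  model <- instance$model
  Rc <- euler_to_matrix(placement$rotation)
  ctr <- subject_center_rest(instance)
  scale <- instance$scale
  Rs <- vector("list", length(model$bones))
  ts <- matrix(NA_real_, length(model$bones), 3)
  root <- path[1]
  t_model <- model$bones[[root]]$rest_offset   # root joint, model frame
  origin <- t_model
  Rcur <- euler_to_matrix(pose[[model$bone_names[root]]] %||% c(0, 0, 0))
  Rs[[root]] <- Rcur; ts[root, ] <- t_model
  if (length(path) > 1) {
    for (k in 2:length(path)) {
      i <- path[k]; p <- path[k - 1]
      t_model <- ts[p, ] + as.numeric(Rs[[p]] %*% model$bones[[i]]$rest_offset)
      Rs[[i]] <- Rs[[p]] %*% euler_to_matrix(pose[[model$bone_names[i]]] %||% c(0, 0, 0))
      ts[i, ] <- t_model
    }
  }
  for (i in path) {
    tw <- origin + (ts[i, ] - origin) * scale
    ts[i, ] <- placement$position + as.numeric(Rc %*% (tw - ctr))
    Rs[[i]] <- Rc %*% Rs[[i]]
  }
  list(R = Rs, t = ts)
}

chain_tip_keypoint <- function(model, chain) {
  tip_bone <- model$bone_names[chain[length(chain)]]
  for (k in model$keypoints) if (k$bone == tip_bone) return(k)
  list(name = tip_bone, bone = tip_bone, offset = c(0, 0, 0))
}

chain_tip_world <- function(instance, placement, pose, chain, wf = NULL) {
  if (is.null(wf)) {
    wf <- chain_world_frames(instance, placement, pose,
                             ancestors_path(instance$model, chain[length(chain)]))
  }
  kp <- chain_tip_keypoint(instance$model, chain)
  i <- chain[length(chain)]
  wf$t[i, ] + as.numeric(wf$R[[i]] %*% (kp$offset * instance$scale))
}

chain_reach <- function(instance, chain) {
  model <- instance$model
  kp <- chain_tip_keypoint(model, chain)
  len <- 0
  for (j in seq_along(chain)) {
    if (j < length(chain)) {
      len <- len + vnorm(model$bones[[chain[j + 1]]]$rest_offset)
    }
  }
  (len + vnorm(kp$offset)) * instance$scale
}

#' Solve a leg chain by cyclic coordinate descent
#'
#' Sweeps the chain from tip to root; at each joint each Euler axis in turn
#' is rotated by the angle that brings the tip closest to the target in the
#' plane perpendicular to that axis, clamped to the joint's limits. Updates
#' never increase the tip-to-target distance. On unreachable targets the
#' chain extends maximally toward the target.
#'
#' @param instance a `synthrig_instance`.
#' @param placement the subject's [place_subject()] result.
#' @param pose named angle list (modified joints are those on the chain).
#' @param chain integer vector of bone indices, root side first.
#' @param target length-3 world target.
#' @param max_iterations maximum CCD sweeps.
#' @param tolerance tip-to-target distance (world units) counted as reached.
#' @return list `pose`, `reached`, `distance`.
#' @export
solve_ik <- function(instance, placement, pose, chain, target,
                     max_iterations = 20, tolerance = 1e-3) {
  model <- instance$model
  lims <- joint_limits(model)
  path <- ancestors_path(model, chain[length(chain)])
  dist <- vnorm(chain_tip_world(instance, placement, pose, chain) - target)
  for (sweep in seq_len(max_iterations)) {
    if (dist <= tolerance) break
    dist_sweep_start <- dist
    for (ci in rev(seq_along(chain))) {
      bi <- chain[ci]
      nm <- model$bone_names[bi]
      for (ax in c(3, 2, 1)) {
        wf <- chain_world_frames(instance, placement, pose, path)
        jpos <- wf$t[bi, ]
        # world direction of the Euler axis being varied: with R = Rz Ry Rx,
        # z pre-multiplies (axis = parent frame e_z), x post-multiplies
        # (axis = bone frame e_x), y sits between (axis = parent * Rz * e_y)
        p <- model$parent_idx[bi]
        Rp <- if (is.na(p)) euler_to_matrix(placement$rotation) else wf$R[[p]]
        ang <- pose[[nm]]
        a_w <- switch(ax,
          as.numeric(wf$R[[bi]] %*% c(1, 0, 0)),
          as.numeric(Rp %*% rot_axis(3, ang[3]) %*% c(0, 1, 0)),
          as.numeric(Rp %*% c(0, 0, 1)))
        tip <- chain_tip_world(instance, placement, pose, chain)
        v1 <- tip - jpos; v2 <- target - jpos
        v1p <- v1 - sum(v1 * a_w) * a_w
        v2p <- v2 - sum(v2 * a_w) * a_w
        if (vnorm(v1p) < 1e-9 || vnorm(v2p) < 1e-9) next
        cosd <- max(-1, min(1, sum(v1p * v2p) / (vnorm(v1p) * vnorm(v2p))))
        sind <- sum(a_w * c(v1p[2] * v2p[3] - v1p[3] * v2p[2],
                            v1p[3] * v2p[1] - v1p[1] * v2p[3],
                            v1p[1] * v2p[2] - v1p[2] * v2p[1])) /
          (vnorm(v1p) * vnorm(v2p))
        delta <- atan2(sind, cosd) * 180 / pi
        lim <- lims[[bi]]
        new_ang <- max(lim[ax, 1], min(lim[ax, 2], ang[ax] + delta))
        if (new_ang == ang[ax]) next
        cand <- pose
        cand[[nm]][ax] <- new_ang
        nd <- vnorm(chain_tip_world(instance, placement, cand, chain) - target)
        if (nd <= dist + 1e-12) {        # CCD monotonicity guard
          pose <- cand
          dist <- nd
        }
      }
    }
    # plateau: a full sweep brought essentially no progress (typical of
    # unreachable targets at maximal extension) - further sweeps are futile
    if (dist_sweep_start - dist < max(tolerance * 1e-2, 1e-9)) break
  }
  list(pose = pose, reached = dist <= tolerance, distance = dist)
}

#' Pose a placed subject
#'
#' Every mesh-interacting leg chain receives a ray-cast foot target and is
#' solved by joint-limited IK (status `grounded`); legs without a target, or
#' legs drawn for intentional mid-air posing, are solved toward a random
#' point within the chain's reach with a restricted number of solver sweeps
#' (status `mid_air`). Mesh-independent joints are each drawn uniformly
#' within their limits.
#'
#' @param instance a `synthrig_instance`.
#' @param placement a [place_subject()] result.
#' @param scene scene list.
#' @param seed integer seed.
#' @param ik_config list: `ik_iterations`, `restricted_iterations`,
#'   `ik_tolerance`, `midair_fraction`, `foot_jitter`.
#' @param subject_index index of this subject in `scene$subjects` (own
#'   proxies are excluded from ray casts).
#' @return list `pose` (named angles), `leg_status` (named
#'   `"grounded"`/`"mid_air"`), class `synthrig_pose`.
#' @export
pose_subject <- function(instance, placement, scene, seed,
                         ik_config = list(), subject_index = 0L) {
  cfg <- utils::modifyList(list(ik_iterations = 100, restricted_iterations = 1,
                                ik_tolerance = 5e-3, midair_fraction = 0.15,
                                foot_jitter = 0.15), ik_config)
  model <- instance$model
  pose <- zero_pose(model)
  status <- character(0)
  for (li in seq_along(model$chains)) {
    chain <- model$chains[[li]]
    foot_rest <- chain_tip_world(instance, placement, pose, chain)
    midair <- with_seed(derive_seed(seed, "midair", li),
                        stats::runif(1) < cfg$midair_fraction)
    target <- if (midair) NULL else {
      ray_cast_foot_target(foot_rest, scene, derive_seed(seed, "foot", li),
                           jitter = cfg$foot_jitter * instance$scale,
                           skip_subject = subject_index)
    }
    if (is.null(target)) {
      # random point within reach of the chain root, not below the surface
      wf <- subject_world_frames(instance, placement, pose)
      root <- wf$t[chain[1], ]
      reach <- chain_reach(instance, chain)
      target <- with_seed(derive_seed(seed, "midair_pt", li), {
        for (k in 1:50) {
          u <- stats::rnorm(3)
          u <- u / vnorm(u) * reach * stats::runif(1)^(1 / 3)
          cand <- root + u
          h <- terrain_height(scene$terrain, cand[1], cand[2])
          if (is.na(h) || cand[3] >= h) break
        }
        cand
      })
      sol <- solve_ik(instance, placement, pose, chain, target,
                      max_iterations = cfg$restricted_iterations,
                      tolerance = cfg$ik_tolerance)
      pose <- sol$pose
      status <- c(status, "mid_air")
    } else {
      sol <- solve_ik(instance, placement, pose, chain, target,
                      max_iterations = cfg$ik_iterations,
                      tolerance = cfg$ik_tolerance)
      pose <- sol$pose
      status <- c(status, if (sol$reached) "grounded" else "mid_air")
    }
  }
  # mesh-independent joints: uniform within limits
  grp <- joint_groups(model)
  lims <- joint_limits(model)
  indep <- which(grp == "mesh_independent")
  for (idx in seq_along(indep)) {
    i <- indep[idx]
    nm <- model$bone_names[i]
    lim <- lims[[i]]
    pose[[nm]] <- with_seed(derive_seed(seed, "indep", idx), {
      vapply(1:3, function(ax) stats::runif(1, lim[ax, 1], lim[ax, 2]), 0)
    })
  }
  names(status) <- vapply(model$chains, function(ch) model$bone_names[ch[length(ch)]], "")
  structure(list(pose = pose, leg_status = status), class = "synthrig_pose")
}
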