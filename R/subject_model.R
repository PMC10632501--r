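# Articulated subject models: armature validation, sidecar I/O, rigid
# forward kinematics, and the digital population sampled at scene time.
#
# A subject model couples a triangle mesh with an armature of rigid bones.
# Every mesh vertex is bound to exactly one bone (rigid binding: arthropod
# exoskeletons make soft deformation unnecessary), each bone carries a joint
# with per-axis angle limits, and named keypoints are fixed offsets in a
# bone's frame.

#' Construct and validate a subject model
#'
#' @param class_name model class label (used as detection class).
#' @param mesh a [mesh()] with per-vertex colors.
#' @param bones list of `list(name, parent, rest_offset)`; `parent` is
#'   `NA` for the single root. `rest_offset` is the joint position in the
#'   parent joint's frame (model units).
#' @param joints list of `list(bone, limits, group)`; `limits` is a 3x2
#'   matrix of per-axis (min, max) degrees; `group` is one of
#'   `"mesh_interacting"`, `"mesh_independent"`, `"fixed"`.
#' @param keypoints list of `list(name, bone, offset)`.
#' @param vertex_bone integer vector, 1-based bone index per mesh vertex.
#' @return a validated `synthrig_subject`.
#' @export
new_subject_model <- function(class_name, mesh, bones, joints, keypoints, vertex_bone) {
  bone_names <- vapply(bones, `[[`, "", "name")
  if (anyDuplicated(bone_names)) {
    stop("validation error: duplicated bone name '",
         bone_names[duplicated(bone_names)][1], "'")
  }
  parents <- vapply(bones, function(b) {
    p <- b$parent
    if (is.null(p) || length(p) == 0 || is.na(p)) NA_character_ else as.character(p)
  }, "")
  roots <- which(is.na(parents))
  if (length(roots) != 1) {
    stop("validation error: bone graph must have exactly one root, found ",
         length(roots))
  }
  parent_idx <- match(parents, bone_names)
  for (i in seq_along(bones)) {
    if (is.na(parents[i])) next
    if (is.na(parent_idx[i])) {
      stop("validation error: bone '", bone_names[i],
           "' references unknown parent '", parents[i], "'")
    }
    # walk up; cycle if we revisit i or exceed bone count
    j <- parent_idx[i]; steps <- 0L
    while (!is.na(j)) {
      if (j == i) stop("validation error: bone cycle involving '", bone_names[i], "'")
      steps <- steps + 1L
      if (steps > length(bones)) stop("validation error: bone cycle detected")
      j <- parent_idx[j]
    }
  }
  if (length(vertex_bone) != nrow(mesh$vertices)) {
    stop("validation error: vertex_bone length (", length(vertex_bone),
         ") != vertex count (", nrow(mesh$vertices), ")")
  }
  if (any(is.na(vertex_bone)) || any(vertex_bone < 1) || any(vertex_bone > length(bones))) {
    stop("validation error: orphan vertex with invalid bone index")
  }
  joint_bones <- vapply(joints, `[[`, "", "bone")
  if (!setequal(joint_bones, bone_names) || length(joints) != length(bones)) {
    stop("validation error: joints must cover every bone exactly once")
  }
  for (j in joints) {
    lim <- j$limits
    if (!is.matrix(lim) || !all(dim(lim) == c(3, 2)) || any(!is.finite(lim)) ||
        any(lim[, 1] > lim[, 2])) {
      stop("validation error: joint limits for '", j$bone,
           "' must be a finite 3x2 (min <= max) matrix")
    }
    if (!j$group %in% c("mesh_interacting", "mesh_independent", "fixed")) {
      stop("validation error: unknown joint group '", j$group, "'")
    }
  }
  kp_names <- vapply(keypoints, `[[`, "", "name")
  if (anyDuplicated(kp_names)) {
    stop("validation error: duplicated keypoint name '",
         kp_names[duplicated(kp_names)][1], "'")
  }
  for (k in keypoints) {
    if (!k$bone %in% bone_names) {
      stop("validation error: keypoint '", k$name,
           "' references unknown bone '", k$bone, "'")
    }
  }
  if (is.null(mesh$colors)) mesh$colors <- matrix(0.5, nrow(mesh$vertices), 3)
  model <- structure(list(
    class_name = class_name, mesh = mesh, bones = bones, joints = joints,
    keypoints = keypoints, vertex_bone = as.integer(vertex_bone),
    bone_names = bone_names, parent_idx = parent_idx),
    class = "synthrig_subject")
  model$chains <- find_leg_chains(model)
  model$proxies <- fit_bone_proxies(model)
  model
}

#' @export
print.synthrig_subject <- function(x, ...) {
  cat(sprintf("<synthrig_subject '%s': %d bones, %d keypoints, %d legs, %d vertices>\n",
              x$class_name, length(x$bones), length(x$keypoints),
              length(x$chains), nrow(x$mesh$vertices)))
  invisible(x)
}

# mesh_interacting joints form contiguous root->tip chains ending in a leaf
# ("foot") bone; collect them as integer index paths ordered root-side first.
find_leg_chains <- function(model) {
  grp <- vapply(model$joints, `[[`, "", "group")
  grp <- grp[match(model$bone_names, vapply(model$joints, `[[`, "", "bone"))]
  inter <- which(grp == "mesh_interacting")
  children <- lapply(seq_along(model$bones), function(i) which(model$parent_idx == i))
  tips <- inter[vapply(inter, function(i) {
    length(intersect(children[[i]], inter)) == 0
  }, TRUE)]
  chains <- lapply(tips, function(tip) {
    path <- integer(0); j <- tip
    while (!is.na(j) && j %in% inter) {
      path <- c(j, path)
      j <- model$parent_idx[j]
    }
    path
  })
  # invariant: every mesh_interacting joint lies on some chain
  used <- unique(unlist(chains))
  if (!setequal(used, inter) && length(inter) > 0) {
    stop("validation error: mesh_interacting joints must form contiguous chains")
  }
  chains
}

# Sphere-chain collision proxy per bone: segment vertices are sliced along
# the bone's principal (longest) axis and each slice fitted with a sphere
# whose radius covers the perpendicular spread — a capsule-style
# approximation that stays tight on elongated segments. Centers are stored
# in the bone's rest frame; the flat list carries the owning bone index.
fit_bone_proxies <- function(model) {
  rest <- rest_joint_positions(model)
  out <- list()
  for (i in seq_along(model$bones)) {
    vi <- which(model$vertex_bone == i)
    if (length(vi) == 0) {
      out[[length(out) + 1L]] <- list(bone = i, center = c(0, 0, 0), radius = 1e-6)
      next
    }
    v <- model$mesh$vertices[vi, , drop = FALSE]
    local <- sweep(v, 2, rest[i, ], "-")
    ext <- apply(local, 2, function(x) diff(range(x)))
    ax <- which.max(ext)
    thick <- max(ext[-ax], 1e-6)
    n_spheres <- max(1L, min(6L, ceiling(ext[ax] / max(thick, 1e-6) / 2)))
    lo <- min(local[, ax])
    step <- ext[ax] / n_spheres
    for (k in seq_len(n_spheres)) {
      sel <- local[, ax] >= lo + (k - 1) * step - 1e-12 &
        local[, ax] <= lo + k * step + 1e-12
      if (!any(sel)) next
      seg <- local[sel, , drop = FALSE]
      ctr <- (apply(seg, 2, min) + apply(seg, 2, max)) / 2
      r <- max(sqrt(rowSums(sweep(seg, 2, ctr, "-")^2)))
      out[[length(out) + 1L]] <- list(bone = i, center = ctr,
                                      radius = max(r, 1e-6))
    }
  }
  out
}

# joint world positions in the rest pose (all angles zero), one row per bone
rest_joint_positions <- function(model) {
  n <- length(model$bones)
  pos <- matrix(0, n, 3)
  for (i in order_topological(model)) {
    p <- model$parent_idx[i]
    base <- if (is.na(p)) c(0, 0, 0) else pos[p, ]
    pos[i, ] <- base + model$bones[[i]]$rest_offset
  }
  pos
}

order_topological <- function(model) {
  n <- length(model$bones)
  done <- logical(n); ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!done & vapply(seq_len(n), function(i) {
      p <- model$parent_idx[i]; is.na(p) || done[p]
    }, TRUE))
    done[ready] <- TRUE
    ord <- c(ord, ready)
  }
  ord
}

#' Write a subject sidecar (armature) file
#'
#' @param model a `synthrig_subject`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(model, path) {
  out <- list(
    class_name = model$class_name,
    bones = lapply(model$bones, function(b) {
      out <- list(name = b$name, rest_offset = as.numeric(b$rest_offset))
      p <- b$parent
      if (!is.null(p) && length(p) == 1 && !is.na(p)) out$parent <- p
      out
    }),
    joints = lapply(model$joints, function(j) list(
      bone = j$bone, limits = unname(apply(j$limits, 1, as.numeric, simplify = FALSE)),
      group = j$group)),
    keypoints = lapply(model$keypoints, function(k) list(
      name = k$name, bone = k$bone, offset = as.numeric(k$offset))),
    vertex_bone = as.integer(model$vertex_bone))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a subject model from a mesh file and its armature sidecar
#'
#' @param mesh_file Wavefront OBJ path (triangles; optional per-vertex color).
#' @param sidecar_file JSON sidecar with `class_name`, `bones`, `joints`,
#'   `keypoints` and `vertex_bone` (see [write_sidecar()]).
#' @return a validated `synthrig_subject`.
#' @export
load_subject <- function(mesh_file, sidecar_file) {
  m <- read_obj(mesh_file)
  if (!file.exists(sidecar_file)) stop("sidecar file not found: ", sidecar_file)
  sc <- jsonlite::read_json(sidecar_file, simplifyVector = FALSE)
  for (key in c("class_name", "bones", "joints", "keypoints", "vertex_bone")) {
    if (is.null(sc[[key]])) stop("sidecar missing required key '", key, "'")
  }
  bones <- lapply(sc$bones, function(b) {
    p <- b$parent
    if (is.null(p) || length(p) != 1 || is.na(p)) p <- NA_character_
    list(name = b$name, parent = p,
         rest_offset = as.numeric(unlist(b$rest_offset)))
  })
  joints <- lapply(sc$joints, function(j) list(
    bone = j$bone,
    limits = do.call(rbind, lapply(j$limits, function(r) as.numeric(unlist(r)))),
    group = j$group))
  keypoints <- lapply(sc$keypoints, function(k) list(
    name = k$name, bone = k$bone, offset = as.numeric(unlist(k$offset))))
  new_subject_model(sc$class_name, m, bones, joints, keypoints,
                    as.integer(unlist(sc$vertex_bone)))
}

# --- population --------------------------------------------------------------

#' Define a simulated population
#'
#' @param entries named list mapping class labels to
#'   `list(model, fraction)`; fractions must sum to one.
#' @param population_size number of subject instances.
#' @param scale_variation fraction `v >= 0`: per-instance scale is uniform on
#'   `[1 - v, 1 + v]` (clipped below at 0.05).
#' @param color_variation list with `hue` (+/- degrees), `brightness`
#'   (+/- additive), `contrast` and `saturation` (multiplier ranges,
#'   length-2).
#' @return a `synthrig_population_spec`.
#' @export
population_spec <- function(entries, population_size,
                            scale_variation = 0.33,
                            color_variation = list(hue = 15, brightness = 0.1,
                                                   contrast = c(0.8, 1.2),
                                                   saturation = c(0.8, 1.2))) {
  fr <- vapply(entries, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9) stop("population fractions must sum to 1")
  if (population_size < 1) stop("population_size must be >= 1")
  if (population_size < sum(fr > 0)) {
    stop("population_size smaller than the number of classes with nonzero fraction")
  }
  if (scale_variation < 0) stop("scale_variation must be >= 0")
  structure(list(entries = entries, population_size = as.integer(population_size),
                 scale_variation = scale_variation, color_variation = color_variation),
            class = "synthrig_population_spec")
}

#' Map an instance id to its unique ID-pass color
#'
#' The bijection `k -> (k mod 256, floor(k/256) mod 256, floor(k/65536)) / 255`
#' is injective for `k` in `[1, 2^24 - 1]` and never yields the reserved
#' background color (0,0,0).
#'
#' @param instance_id integer `>= 1`.
#' @return RGB triple in `[0, 1]`.
#' @export
id_color <- function(instance_id) {
  k <- as.numeric(instance_id)
  if (any(k < 1) || any(k > 2^24 - 1)) stop("instance_id out of [1, 2^24 - 1]")
  cbind(k %% 256, floor(k / 256) %% 256, floor(k / 65536)) / 255
}

#' Build the digital population for one run
#'
#' Class counts follow `round(fraction * size)` with largest-remainder
#' correction so they always sum to `population_size`. Scale and color
#' modifiers are drawn per instance; the result is identical under an
#' identical seed.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @return list of `synthrig_instance` (fields `instance_id`, `class_name`,
#'   `model`, `scale`, `color_mods`, `id_color`).
#' @export
build_population <- function(spec, seed) {
  fr <- vapply(spec$entries, `[[`, 0, "fraction")
  n <- spec$population_size
  raw <- fr * n
  counts <- floor(raw + 0.5)               # round half up, deterministic
  rem <- raw - floor(raw)
  diff <- n - sum(counts)
  if (diff != 0) {
    ord <- order(rem, decreasing = diff > 0)
    for (i in seq_len(abs(diff))) {
      j <- ord[i]
      counts[j] <- counts[j] + sign(diff)
    }
  }
  classes <- rep(names(spec$entries), counts)
  cv <- spec$color_variation
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      scale <- max(0.05, stats::runif(1, 1 - spec$scale_variation, 1 + spec$scale_variation))
      mods <- list(
        hue = stats::runif(1, -cv$hue, cv$hue),
        brightness = stats::runif(1, -cv$brightness, cv$brightness),
        contrast = stats::runif(1, cv$contrast[1], cv$contrast[2]),
        saturation = stats::runif(1, cv$saturation[1], cv$saturation[2]))
      structure(list(
        instance_id = i,
        class_name = classes[i],
        model = spec$entries[[classes[i]]]$model,
        scale = scale,
        color_mods = mods,
        id_color = as.numeric(id_color(i))),
        class = "synthrig_instance")
    })
  })
}

#' Apply appearance modifiers to a color
#'
#' Hue is rotated and saturation scaled in HSV space; brightness is an
#' additive offset and contrast the affine map `(x - 0.5) * c + 0.5`,
#' applied in that order. The result is clipped to `[0, 1]^3`.
#'
#' @param base_color RGB triple or n x 3 matrix in `[0, 1]`.
#' @param mods list with `hue` (degrees), `brightness`, `contrast`,
#'   `saturation`.
#' @return color(s) of the same shape, clipped to `[0, 1]`.
#' @export
apply_color_mods <- function(base_color, mods) {
  x <- if (is.matrix(base_color)) base_color else matrix(base_color, 1)
  hsv <- grDevices::rgb2hsv(t(x), maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + mods$hue / 360) %% 1
  hsv[2, ] <- pmin(pmax(hsv[2, ] * mods$saturation, 0), 1)
  rgb <- hsv_to_rgb(hsv[1, ], hsv[2, ], hsv[3, ])
  rgb <- rgb + mods$brightness
  rgb <- (rgb - 0.5) * mods$contrast + 0.5
  rgb <- pmin(pmax(rgb, 0), 1)
  if (is.matrix(base_color)) rgb else as.numeric(rgb)
}

identity_mods <- function() list(hue = 0, brightness = 0, contrast = 1, saturation = 1)

# continuous (unquantized) HSV -> RGB; h in [0,1) turns, s, v in [0,1]
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  for (k in seq_along(h)) {
    rgb <- switch(as.integer(i[k] %% 6) + 1L,
                  c(v[k], t[k], p[k]), c(q[k], v[k], p[k]), c(p[k], v[k], t[k]),
                  c(p[k], q[k], v[k]), c(t[k], p[k], v[k]), c(v[k], p[k], q[k]))
    r[k] <- rgb[1]; g[k] <- rgb[2]; b[k] <- rgb[3]
  }
  cbind(r, g, b)
}

# --- forward kinematics ------------------------------------------------------

#' Zero pose for a model
#' @param model a `synthrig_subject`.
#' @return named list of length-3 zero angle vectors, one per non-fixed joint.
#' @export
zero_pose <- function(model) {
  grp <- joint_groups(model)
  nm <- model$bone_names[grp != "fixed"]
  stats::setNames(rep(list(c(0, 0, 0)), length(nm)), nm)
}

joint_groups <- function(model) {
  jb <- vapply(model$joints, `[[`, "", "bone")
  grp <- vapply(model$joints, `[[`, "", "group")
  grp[match(model$bone_names, jb)]
}

joint_limits <- function(model) {
  jb <- vapply(model$joints, `[[`, "", "bone")
  lims <- lapply(model$joints, `[[`, "limits")
  lims[match(model$bone_names, jb)]
}

check_pose_limits <- function(model, pose) {
  lims <- joint_limits(model)
  grp <- joint_groups(model)
  for (i in seq_along(model$bone_names)) {
    nm <- model$bone_names[i]
    ang <- pose[[nm]]
    if (grp[i] == "fixed") {
      if (!is.null(ang) && any(ang != 0)) {
        stop("pose error: joint '", nm, "' is fixed but has nonzero angles")
      }
      next
    }
    if (is.null(ang)) stop("pose error: missing angles for joint '", nm, "'")
    lim <- lims[[i]]
    for (ax in 1:3) {
      if (ang[ax] < lim[ax, 1] - 1e-9 || ang[ax] > lim[ax, 2] + 1e-9) {
        stop(sprintf("pose error: joint '%s' axis %d angle %.3f outside limits [%.3f, %.3f]",
                     nm, ax, ang[ax], lim[ax, 1], lim[ax, 2]))
      }
    }
  }
  invisible(TRUE)
}

# Per-bone world frames for a pose: list of (R 3x3, t 3) composed
# parent-transform * translate(rest_offset) * joint_rotation, then uniform
# scale about the root joint.
bone_frames <- function(model, pose, scale = 1) {
  n <- length(model$bones)
  Rs <- vector("list", n); ts <- matrix(0, n, 3)
  for (i in order_topological(model)) {
    p <- model$parent_idx[i]
    ang <- pose[[model$bone_names[i]]] %||% c(0, 0, 0)
    Rj <- euler_to_matrix(ang)
    if (is.na(p)) {
      Rs[[i]] <- Rj
      ts[i, ] <- model$bones[[i]]$rest_offset
    } else {
      Rs[[i]] <- Rs[[p]] %*% Rj
      ts[i, ] <- ts[p, ] + as.numeric(Rs[[p]] %*% model$bones[[i]]$rest_offset)
    }
  }
  root <- which(is.na(model$parent_idx))
  origin <- ts[root, ]
  for (i in seq_len(n)) ts[i, ] <- origin + (ts[i, ] - origin) * scale
  list(R = Rs, t = ts, scale = scale)
}

#' Pose a subject model by forward kinematics
#'
#' Vertices and keypoints move rigidly with their bone; each bone frame is
#' the parent frame composed with the bone's rest offset and its joint
#' rotation; uniform scale is applied about the root joint. Within-bone
#' pairwise distances are preserved exactly (up to the uniform scale).
#'
#' @param model a `synthrig_subject`.
#' @param pose named list of per-joint XYZ Euler angles (degrees); every
#'   non-fixed joint must be present and within its limits.
#' @param scale uniform scale factor.
#' @return list with `vertices` (n x 3), `keypoints` (named k x 3 matrix of
#'   world-frame positions), `frames` (per-bone transforms).
#' @export
pose_mesh <- function(model, pose, scale = 1) {
  check_pose_limits(model, pose)
  fr <- bone_frames(model, pose, scale)
  rest <- rest_joint_positions(model)
  v <- model$mesh$vertices
  out <- matrix(0, nrow(v), 3)
  for (i in seq_along(model$bones)) {
    vi <- which(model$vertex_bone == i)
    if (length(vi) == 0) next
    local <- sweep(v[vi, , drop = FALSE], 2, rest[i, ], "-") * scale
    out[vi, ] <- sweep(local %*% t(fr$R[[i]]), 2, fr$t[i, ], "+")
  }
  kp <- t(vapply(model$keypoints, function(k) {
    i <- match(k$bone, model$bone_names)
    fr$t[i, ] + as.numeric(fr$R[[i]] %*% (k$offset * scale))
  }, numeric(3)))
  rownames(kp) <- vapply(model$keypoints, `[[`, "", "name")
  list(vertices = out, keypoints = kp, frames = fr)
}
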