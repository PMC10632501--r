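# Built-in primitive meshes: the default asset library and the articulated
# test subject. Everything is generated in code so no binary fixtures ship
# with the package.

#' Axis-aligned box mesh
#' @param size length-3 vector of edge lengths.
#' @param center length-3 center position.
#' @param color length-3 RGB, recycled per vertex.
#' @return a [mesh()].
#' @export
make_box <- function(size = c(1, 1, 1), center = c(0, 0, 0), color = c(0.5, 0.5, 0.5)) {
  h <- size / 2
  corners <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]), z = c(-h[3], h[3])))
  v <- sweep(corners, 2, center, "+")
  # 12 triangles over the 8 expand.grid-ordered corners
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),  # -y? (faces chosen for consistent outward winding)
    c(2, 8, 4), c(2, 6, 8),
    c(1, 5, 6), c(1, 6, 2),
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),
    c(5, 7, 8), c(5, 8, 6))
  mesh(v, f, matrix(color, 8, 3, byrow = TRUE))
}

#' Cylinder mesh (axis along Z)
#' @param radius,height cylinder dimensions.
#' @param segments number of circumference segments.
#' @param center length-3 center position.
#' @param color RGB recycled per vertex.
#' @return a [mesh()].
#' @export
make_cylinder <- function(radius = 0.5, height = 1, segments = 12,
                          center = c(0, 0, 0), color = c(0.5, 0.5, 0.5)) {
  ang <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  ring <- cbind(cos(ang) * radius, sin(ang) * radius)
  v <- rbind(
    cbind(ring, -height / 2), cbind(ring, height / 2),
    c(0, 0, -height / 2), c(0, 0, height / 2))
  n <- segments
  side <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- i %% n + 1L
    rbind(c(i, j, n + j), c(i, n + j, n + i))
  }))
  capb <- do.call(rbind, lapply(seq_len(n), function(i) c(2L * n + 1L, i %% n + 1L, i)))
  capt <- do.call(rbind, lapply(seq_len(n), function(i) c(2L * n + 2L, n + i, n + i %% n + 1L)))
  v <- sweep(v, 2, center, "+")
  mesh(v, rbind(side, capb, capt), matrix(color, nrow(v), 3, byrow = TRUE))
}

#' Icosphere mesh
#' @param radius sphere radius.
#' @param subdivisions number of subdivision rounds (0-3 sensible).
#' @param color RGB recycled per vertex.
#' @return a [mesh()].
#' @export
make_icosphere <- function(radius = 0.5, subdivisions = 1, color = c(0.5, 0.5, 0.5)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    newf <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[[length(newf) + 1L]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, newf)
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  mesh(v, f, matrix(color, nrow(v), 3, byrow = TRUE))
}

#' Pebble mesh: an icosphere with seeded radial noise
#' @param radius base radius.
#' @param roughness relative radial perturbation amplitude.
#' @param seed integer seed for the perturbation.
#' @param color RGB recycled per vertex.
#' @return a [mesh()].
#' @export
make_pebble <- function(radius = 0.5, roughness = 0.25, seed = 1, color = c(0.5, 0.5, 0.5)) {
  m <- make_icosphere(radius, subdivisions = 1, color = color)
  r <- with_seed(seed, stats::runif(nrow(m$vertices), 1 - roughness, 1 + roughness))
  m$vertices <- m$vertices * r
  m
}

#' Default primitive asset library
#'
#' Small library of normalized untextured meshes used as the default
#' scatterer asset set.
#'
#' @param seed seed for pebble perturbation.
#' @return named list of normalized meshes (largest extent 1).
#' @export
primitive_asset_library <- function(seed = 1) {
  lapply(list(
    box = make_box(c(1, 0.8, 0.6)),
    slab = make_box(c(1, 1, 0.15)),
    cylinder = make_cylinder(0.3, 1),
    sphere = make_icosphere(0.5, 1),
    pebble = make_pebble(0.5, 0.25, seed = seed)
  ), normalize_mesh)
}

# --- articulated test subject ------------------------------------------------

leg_dirs <- function() {
  # 3 legs per side, attachment x positions fore/mid/hind
  expand.grid(x = c(0.6, 0, -0.6), side = c(1, -1))
}

#' Built-in articulated "stick" subject
#'
#' An elongated body with six two-segment legs (13 bones, 6 mesh-interacting
#' chains each ending in a foot) used as the default test subject. With
#' `antennae = TRUE` two extra mesh-independent antenna bones are added.
#'
#' @param antennae add two mesh-independent antenna bones.
#' @param color base body RGB.
#' @return a `synthrig_subject` (see [load_subject()]).
#' @export
make_stick_subject <- function(antennae = FALSE, color = c(0.55, 0.35, 0.2)) {
  segs <- list()
  bones <- list(list(name = "body", parent = NA_character_, rest_offset = c(0, 0, 0)))
  joints <- list(list(bone = "body", limits = matrix(0, 3, 2), group = "fixed"))
  vertex_bone <- integer(0)

  add_segment <- function(m, bone_index) {
    segs[[length(segs) + 1L]] <<- m
    vertex_bone <<- c(vertex_bone, rep(bone_index, nrow(m$vertices)))
  }

  body <- make_box(c(2, 0.4, 0.35), center = c(0, 0, 0), color = color)
  add_segment(body, 1L)

  ld <- leg_dirs()
  upper_off <- c(0, 0.45, -0.15)   # outward along +/- y, slightly down
  lower_off <- c(0, 0.15, -0.45)   # down to the foot
  keypoints <- list(
    list(name = "head", bone = "body", offset = c(1, 0, 0.05)),
    list(name = "thorax", bone = "body", offset = c(0, 0, 0.175)),
    list(name = "abdomen", bone = "body", offset = c(-1, 0, 0.05)))

  lim_wide <- cbind(rep(-90, 3), rep(90, 3))
  for (i in seq_len(nrow(ld))) {
    s <- ld$side[i]
    attach <- c(ld$x[i], s * 0.2, -0.05)
    up_name <- sprintf("leg%d_upper", i)
    lo_name <- sprintf("leg%d_lower", i)
    uo <- upper_off * c(1, s, 1)
    lo <- lower_off * c(1, s, 1)
    bones[[length(bones) + 1L]] <- list(name = up_name, parent = "body", rest_offset = attach)
    joints[[length(joints) + 1L]] <- list(bone = up_name, limits = lim_wide, group = "mesh_interacting")
    bones[[length(bones) + 1L]] <- list(name = lo_name, parent = up_name, rest_offset = uo)
    joints[[length(joints) + 1L]] <- list(bone = lo_name, limits = lim_wide, group = "mesh_interacting")
    iu <- length(bones) - 1L; il <- length(bones)
    # thin box along each segment, axis-aligned approximation rotated onto the segment
    seg_mesh <- function(from, to, thick) {
      d <- to - from; len <- vnorm(d)
      m <- make_box(c(thick, thick, len), center = c(0, 0, len / 2), color = color * 0.9)
      z <- c(0, 0, 1); dn <- d / len
      ax <- c(z[2] * dn[3] - z[3] * dn[2], z[3] * dn[1] - z[1] * dn[3], z[1] * dn[2] - z[2] * dn[1])
      R <- if (vnorm(ax) < 1e-9) diag(3) * sign(sum(z * dn)) else rot_about_axis(ax, acos(max(-1, min(1, sum(z * dn)))))
      mesh_transform(m, rotation = R, translation = from)
    }
    add_segment(seg_mesh(attach, attach + uo, 0.08), iu)
    add_segment(seg_mesh(attach + uo, attach + uo + lo, 0.06), il)
    keypoints[[length(keypoints) + 1L]] <- list(name = sprintf("leg%d_foot", i), bone = lo_name, offset = lo)
  }

  if (antennae) {
    for (s in c(1, -1)) {
      nm <- if (s > 0) "antenna_l" else "antenna_r"
      off <- c(0.9, s * 0.1, 0.15)
      bones[[length(bones) + 1L]] <- list(name = nm, parent = "body", rest_offset = off)
      joints[[length(joints) + 1L]] <- list(bone = nm, limits = cbind(rep(-30, 3), rep(30, 3)),
                                            group = "mesh_independent")
      ant <- make_box(c(0.5, 0.03, 0.03), center = c(0.25, 0, 0), color = color * 0.8)
      add_segment(mesh_transform(ant, translation = off), length(bones))
      keypoints[[length(keypoints) + 1L]] <- list(name = paste0(nm, "_tip"), bone = nm, offset = c(0.5, 0, 0))
    }
  }

  m <- merge_meshes(segs)
  new_subject_model(class_name = "stick", mesh = m, bones = bones, joints = joints,
                    keypoints = keypoints, vertex_bone = vertex_bone)
}

#' Write the built-in stick subject as OBJ + sidecar files
#'
#' Convenience for tests and examples of the file-based loading path.
#'
#' @param dir output directory.
#' @param antennae passed to [make_stick_subject()].
#' @return named list with `mesh` and `sidecar` paths.
#' @export
write_stick_subject <- function(dir, antennae = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subj <- make_stick_subject(antennae = antennae)
  mesh_path <- file.path(dir, "stick.obj")
  sidecar_path <- file.path(dir, "stick.json")
  write_obj(subj$mesh, mesh_path)
  write_sidecar(subj, sidecar_path)
  list(mesh = mesh_path, sidecar = sidecar_path)
}
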