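# Triangle-mesh container and Wavefront OBJ I/O.
#
# A mesh is a plain list: vertices (n x 3 numeric), triangles (m x 3 integer,
# 1-based), and optional colors (n x 3 in [0,1]). OBJ vertex colors use the
# widely supported extended "v x y z r g b" line form.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions (model units).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param colors optional n x 3 matrix of per-vertex RGB in `[0, 1]`.
#' @return an object of class `synthrig_mesh`.
#' @export
mesh <- function(vertices, triangles, colors = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) < 1) stop("mesh must contain at least one triangle")
  if (any(triangles < 1) || any(triangles > nrow(vertices))) {
    stop("triangle indices out of range")
  }
  if (!is.null(colors)) {
    colors <- matrix(as.numeric(colors), ncol = 3)
    if (nrow(colors) != nrow(vertices)) stop("colors must match vertex count")
  }
  structure(list(vertices = vertices, triangles = triangles, colors = colors),
            class = "synthrig_mesh")
}

#' @export
print.synthrig_mesh <- function(x, ...) {
  cat(sprintf("<synthrig_mesh: %d vertices, %d triangles%s>\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$colors)) "" else ", per-vertex color"))
  invisible(x)
}

#' Read a Wavefront OBJ file as a triangle mesh
#'
#' Supports `v x y z [r g b]` vertex lines and `f` faces with any of the
#' `v`, `v/vt`, `v//vn`, `v/vt/vn` index styles; polygons are fan
#' triangulated. Normals/texcoords are ignored (normals are recomputed per
#' face at render time).
#'
#' @param path OBJ file path.
#' @return a [mesh()].
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vparts <- list(); fparts <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "v ")) vparts[[length(vparts) + 1L]] <- ln
    else if (startsWith(ln, "f ")) fparts[[length(fparts) + 1L]] <- ln
  }
  if (length(vparts) == 0 || length(fparts) == 0) {
    stop("malformed OBJ: no vertices or no faces in ", path)
  }
  vt <- lapply(vparts, function(ln) {
    x <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]][-1]))
    if (length(x) < 3 || anyNA(x[1:3])) stop("malformed OBJ vertex line: ", ln)
    x
  })
  verts <- t(vapply(vt, function(x) x[1:3], numeric(3)))
  has_col <- all(vapply(vt, length, 0L) >= 6)
  cols <- if (has_col) t(vapply(vt, function(x) x[4:6], numeric(3))) else NULL
  tris <- list()
  for (ln in fparts) {
    toks <- strsplit(ln, "\\s+")[[1]][-1]
    idx <- vapply(toks, function(tok) {
      i <- suppressWarnings(as.integer(strsplit(tok, "/")[[1]][1]))
      if (is.na(i)) stop("malformed OBJ face token: ", tok)
      if (i < 0) i <- nrow(verts) + 1L + i
      i
    }, integer(1))
    if (length(idx) < 3) stop("malformed OBJ face line: ", ln)
    for (k in 2:(length(idx) - 1L)) {
      tris[[length(tris) + 1L]] <- c(idx[1], idx[k], idx[k + 1L])
    }
  }
  mesh(verts, do.call(rbind, tris), cols)
}

#' Write a triangle mesh as a Wavefront OBJ file
#'
#' @param m a [mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- m$vertices
  if (is.null(m$colors)) {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  } else {
    cc <- m$colors
    writeLines(sprintf("v %.9g %.9g %.9g %.9g %.9g %.9g",
                       v[, 1], v[, 2], v[, 3], cc[, 1], cc[, 2], cc[, 3]), con)
  }
  tr <- m$triangles
  writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}

#' Normalize a mesh so its largest axis-aligned extent equals one
#'
#' Asset meshes are pre-normalized before scattering so that a scatterer's
#' size range acts on comparable units across assets.
#'
#' @param m a [mesh()].
#' @return the rescaled mesh, centered on the origin in X/Y with its base at
#'   the minimum Z it had after scaling.
#' @export
normalize_mesh <- function(m) {
  v <- m$vertices
  ext <- apply(v, 2, function(x) diff(range(x)))
  s <- max(ext)
  if (s <= 0) stop("degenerate mesh: zero extent")
  v <- v / s
  ctr <- colMeans(v)
  v[, 1] <- v[, 1] - ctr[1]
  v[, 2] <- v[, 2] - ctr[2]
  m$vertices <- v
  m
}

mesh_transform <- function(m, rotation = diag(3), scale = 1, translation = c(0, 0, 0)) {
  m$vertices <- sweep(m$vertices %*% t(rotation) * scale, 2, translation, "+")
  m
}

merge_meshes <- function(meshes) {
  off <- 0L
  vs <- list(); ts <- list(); cs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    ts[[length(ts) + 1L]] <- m$triangles + off
    cs[[length(cs) + 1L]] <- if (is.null(m$colors)) {
      matrix(0.5, nrow(m$vertices), 3)
    } else m$colors
    off <- off + nrow(m$vertices)
  }
  mesh(do.call(rbind, vs), do.call(rbind, ts), do.call(rbind, cs))
}
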