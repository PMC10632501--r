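# Rotation and ray-geometry helpers shared by placement, posing and rendering.
# Convention: right-handed world with Z up; Euler angles in degrees, applied
# intrinsically in X-Y-Z order (roll, pitch, yaw): R = Rz %*% Ry %*% Rx.

deg2rad <- function(d) d * pi / 180

#' Rotation matrix about a principal axis
#' @param axis 1, 2 or 3 for X, Y, Z.
#' @param angle_deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  switch(axis,
    matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
    matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3))
}

#' Euler XYZ rotation matrix
#' @param angles_deg length-3 vector (x, y, z) in degrees.
#' @return 3x3 rotation matrix `Rz %*% Ry %*% Rx`.
#' @export
euler_to_matrix <- function(angles_deg) {
  rot_axis(3, angles_deg[3]) %*% rot_axis(2, angles_deg[2]) %*% rot_axis(1, angles_deg[1])
}

# Rodrigues rotation about an arbitrary unit axis
rot_about_axis <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  c <- cos(angle_rad); s <- sin(angle_rad)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  K <- matrix(c(0, z, -y, -z, 0, x, y, -x, 0), 3, 3)
  diag(3) + s * K + (1 - c) * (K %*% K)
}

vnorm <- function(v) sqrt(sum(v^2))

#' Ray-sphere intersection
#'
#' @param origin,dir ray origin and unit direction.
#' @param center,radius sphere.
#' @return smallest positive t, or `Inf` when the ray misses.
#' @keywords internal
ray_sphere <- function(origin, dir, center, radius) {
  oc <- origin - center
  b <- sum(oc * dir)
  disc <- b * b - (sum(oc * oc) - radius^2)
  if (disc < 0) return(Inf)
  sq <- sqrt(disc)
  t1 <- -b - sq
  t2 <- -b + sq
  if (t1 > 1e-9) t1 else if (t2 > 1e-9) t2 else Inf
}

#' Ray-AABB intersection (slab method)
#'
#' @param origin,dir ray origin and direction.
#' @param lo,hi box corners.
#' @return smallest positive t, or `Inf`.
#' @keywords internal
ray_aabb <- function(origin, dir, lo, hi) {
  tmin <- -Inf; tmax <- Inf
  for (k in 1:3) {
    if (abs(dir[k]) < 1e-12) {
      if (origin[k] < lo[k] || origin[k] > hi[k]) return(Inf)
    } else {
      t1 <- (lo[k] - origin[k]) / dir[k]
      t2 <- (hi[k] - origin[k]) / dir[k]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      tmin <- max(tmin, t1); tmax <- min(tmax, t2)
      if (tmin > tmax) return(Inf)
    }
  }
  if (tmax < 1e-9) return(Inf)
  if (tmin > 1e-9) tmin else tmax
}

sphere_aabb_overlap <- function(center, radius, lo, hi) {
  d2 <- 0
  for (k in 1:3) {
    if (center[k] < lo[k]) d2 <- d2 + (lo[k] - center[k])^2
    else if (center[k] > hi[k]) d2 <- d2 + (center[k] - hi[k])^2
  }
  d2 <= radius^2
}
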