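# Rigid-body geometry primitives shared by every module.
#
# Conventions (documented once, used everywhere):
#   * angles cross module boundaries in degrees, are used internally in radians;
#   * rotation matrices act on column vectors, p' = R %*% p;
#   * a rigid transform is a 4x4 homogeneous matrix, rotation block [1:3,1:3],
#     translation [1:3,4]; composition is plain matrix product;
#   * a jump 6-vector (x, y, z, angle_x, angle_y, angle_z) maps to the local
#     transform p' = Rz(az) Ry(ay) Rx(ax) p + t, i.e. rotation about the local
#     x, then y, then z axes (all through the local origin), then translation
#     along the local axes.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the Cartesian axes, acting on column vectors.
#'
#' @param deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @keywords internal
#' @name elementary-rotations
NULL

rot_x <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# rotation about an arbitrary unit axis (Rodrigues)
rot_axis <- function(axis, deg) {
  u <- unitize(axis)
  a <- deg2rad(deg)
  K <- skew3(u)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# derivative of the elementary rotation with respect to its angle (per radian)
drot_x <- function(deg) rot_x(deg) %*% skew3(c(1, 0, 0))
drot_y <- function(deg) rot_y(deg) %*% skew3(c(0, 1, 0))
drot_z <- function(deg) rot_z(deg) %*% skew3(c(0, 0, 1))

## ---- homogeneous transforms ------------------------------------------------

tf_new <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

tf_identity <- function() diag(4)

tf_rot <- function(T) T[1:3, 1:3, drop = FALSE]
tf_trans <- function(T) T[1:3, 4]

tf_inverse <- function(T) {
  R <- tf_rot(T)
  tf_new(t(R), -t(R) %*% tf_trans(T))
}

# apply a 4x4 transform to an n x 3 coordinate matrix
tf_apply <- function(T, xyz) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(tf_rot(T)), 2, -tf_trans(T))
}

# local jump transform for a 6-vector (x,y,z in Angstrom, angles in degrees)
jump_transform <- function(v) {
  stopifnot(length(v) == 6)
  R <- rot_z(v[6]) %*% rot_y(v[5]) %*% rot_x(v[4])
  tf_new(R, v[1:3])
}

# derivative of jump_transform with respect to one named dof component.
# Translations are per Angstrom; angles per DEGREE (so finite differences in
# degrees match directly).
jump_transform_deriv <- function(v, dof) {
  Z <- matrix(0, 4, 4)
  if (dof %in% c("x", "y", "z")) {
    Z[1:3, 4] <- switch(dof, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
    return(Z)
  }
  dR <- switch(dof,
    angle_x = rot_z(v[6]) %*% rot_y(v[5]) %*% drot_x(v[4]),
    angle_y = rot_z(v[6]) %*% drot_y(v[5]) %*% rot_x(v[4]),
    angle_z = drot_z(v[6]) %*% rot_y(v[5]) %*% rot_x(v[4]),
    stop("unknown dof component: ", dof))
  Z[1:3, 1:3] <- dR * pi / 180
  Z
}

## ---- superposition and rotation analysis ----------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum |R x_i + t - y_i|^2`, i.e. the rigid transform mapping `x` onto `y`.
#'
#' @param x,y n x 3 coordinate matrices with matched rows (n >= 3).
#' @return A list with elements `R` (3x3 rotation), `t` (length-3 translation),
#'   `rmsd` (the residual root-mean-square deviation) and `tf` (the same
#'   transform as a 4x4 matrix).
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y), nrow(x) >= 3)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(x %*% t(R), 2, -t)
  list(R = R, t = t,
       rmsd = sqrt(mean(rowSums((fit - y)^2))),
       tf = tf_new(R, t))
}

# extract (axis, angle in degrees) from a rotation matrix; axis sign chosen so
# the angle is in [0, 180].
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  ca <- max(-1, min(1, (tr - 1) / 2))
  ang <- acos(ca)
  if (ang < 1e-8) return(list(axis = c(0, 0, 1), angle = 0))
  if (pi - ang < 1e-6) {
    # 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    axis <- unitize(B[, i])
  } else {
    axis <- unitize(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
  }
  list(axis = axis, angle = rad2deg(ang))
}

# a point on the axis of a (non-screw) rotation R about unknown center with
# translation t: solves (I - R) c = t in the least-squares sense.
rotation_axis_point <- function(R, t) {
  A <- diag(3) - R
  s <- svd(A)
  dinv <- ifelse(s$d > 1e-8, 1 / s$d, 0)
  as.vector(s$v %*% (dinv * (t(s$u) %*% t)))
}

## ---- dihedrals -------------------------------------------------------------

# signed dihedral angle a-b-c-d in degrees, in (-180, 180]
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitize(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

bond_angle <- function(a, b, c) {
  u <- unitize(a - b); v <- unitize(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# place a new atom given three reference atoms (NeRF): the new atom is bonded
# to `c` with the given bond length, forms angle(new-c-b) and dihedral
# (new-c-b-a), angles in degrees.
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- deg2rad(angle); ph <- deg2rad(torsion)
  bc <- unitize(c - b)
  n <- unitize(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          -length * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## ---- uniform rotations -----------------------------------------------------

# uniform random rotation matrix via Shoemake's uniform-quaternion method,
# consuming three uniforms from the current RNG stream.
random_rotation_matrix <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# decompose a rotation matrix into (angle_x, angle_y, angle_z) degrees such
# that R = Rz(az) Ry(ay) Rx(ax), matching jump_transform().
euler_zyx_from_matrix <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ay <- asin(sy)
  if (abs(cos(ay)) > 1e-9) {
    ax <- atan2(R[3, 2], R[3, 3])
    az <- atan2(R[2, 1], R[1, 1])
  } else {
    ax <- atan2(-R[2, 3], R[2, 2])
    az <- 0
  }
  rad2deg(c(angle_x = ax, angle_y = ay, angle_z = az))
}
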