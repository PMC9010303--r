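# Internal rigid-body geometry helpers shared by the frame, stacking and
# synthesis code. All rotations are 3x3 proper orthonormal matrices acting on
# column vectors; coordinates are in Angstrom, angles in radians unless a
# function name says otherwise.

#' @importFrom stats uniroot
NULL

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.clamp1 <- function(x) max(-1, min(1, x))

# Rodrigues rotation about unit axis n by angle theta.
.rot_axis <- function(n, theta) {
  n <- .unit(n)
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

.rot_z <- function(theta) .rot_axis(c(0, 0, 1), theta)
.rot_y <- function(theta) .rot_axis(c(0, 1, 0), theta)

# Axis and angle of a rotation matrix; angle in [0, pi]. For angle ~ 0 the
# axis is arbitrary and (0,0,1) is returned.
.axis_angle <- function(R) {
  theta <- acos(.clamp1((sum(diag(R)) - 1) / 2))
  if (theta < 1e-12) return(list(axis = c(0, 0, 1), angle = 0))
  if (pi - theta < 1e-8) {
    # near 180 deg: extract axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    i <- which.max(ax)
    sgn <- c(1, 1, 1)
    if (i == 1) {
      sgn[2] <- sign(B[1, 2] + 1e-300); sgn[3] <- sign(B[1, 3] + 1e-300)
    } else if (i == 2) {
      sgn[1] <- sign(B[1, 2] + 1e-300); sgn[3] <- sign(B[2, 3] + 1e-300)
    } else {
      sgn[1] <- sign(B[1, 3] + 1e-300); sgn[2] <- sign(B[2, 3] + 1e-300)
    }
    return(list(axis = .unit(ax * sgn), angle = theta))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  list(axis = ax, angle = theta)
}

# Principal square root of a rotation (half the angle, same axis).
.rot_sqrt <- function(R) {
  aa <- .axis_angle(R)
  .rot_axis(aa$axis, aa$angle / 2)
}

# Half-step rotation S such that the symmetric frame pair R1 = M S^-1,
# R2 = M S decomposes (under the quaternion-midpoint convention used by
# step_parameters) into exactly the requested tilt and twist. Closed form for
# bend azimuth phi = 0; for phi != 0 the inner twist parameter is solved
# numerically because the projection-based twist is azimuth-dependent.
.half_step <- function(tilt, twist, azimuth = 0) {
  stopifnot(tilt >= 0, tilt < pi)
  if (abs(azimuth) < 1e-12) return(.half_step0(tilt, twist))
  if (tilt < 1e-12 && abs(twist) < 1e-12) return(diag(3))
  f <- function(w) {
    S <- .rot_z(azimuth) %*% .half_step0(tilt, w) %*% .rot_z(-azimuth)
    .twist_of_pair(t(S), S) - twist
  }
  lim <- pi - 1e-6
  w <- uniroot(f, c(-lim, lim), tol = 1e-14)$root
  .rot_z(azimuth) %*% .half_step0(tilt, w) %*% .rot_z(-azimuth)
}

.half_step0 <- function(tilt, twist) {
  a <- sin(tilt / 2)
  b <- tan(twist / 2)
  s2 <- (a^2 + b^2) / (1 + b^2)
  sth <- sqrt(s2)
  if (sth < 1e-15) return(diag(3))
  th <- asin(min(1, sth))
  nz <- b * cos(th) / sin(th)
  rho <- sqrt(max(0, 1 - nz^2))
  .rot_axis(c(rho, 0, nz), th)
}

# Signed twist (radians) of the symmetric pair (R1, R2) about the midpoint
# z axis, following the same projection convention as step_parameters.
.twist_of_pair <- function(R1, R2) {
  H <- .rot_sqrt(t(R1) %*% R2)
  M <- R1 %*% H
  zm <- M[, 3]
  p1 <- R1[, 2] - sum(R1[, 2] * zm) * zm
  p2 <- R2[, 2] - sum(R2[, 2] * zm) * zm
  p1 <- .unit(p1); p2 <- .unit(p2)
  atan2(sum(zm * .cross3(p1, p2)), .clamp1(sum(p1 * p2)))
}

# Scoped RNG: run expr with a given seed without disturbing the caller's
# random stream.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
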