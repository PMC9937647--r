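# Angle and unit-vector helpers. Angles are degrees at every exported
# interface and radians only inside closed-form expressions.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Spherical to Cartesian embedding on the unit sphere
#'
#' Maps dipole angles to unit vectors, `x = sin(theta)cos(phi)`,
#' `y = sin(theta)sin(phi)`, `z = cos(theta)`.
#'
#' @param theta_deg Inclination from the optical (z) axis, degrees.
#' @param phi_deg In-plane rotation angle, degrees.
#' @return Numeric matrix with columns `x`, `y`, `z`, one row per input angle.
#' @export
sph_to_cart <- function(theta_deg, phi_deg) {
  th <- deg2rad(theta_deg)
  ph <- deg2rad(phi_deg)
  cbind(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
}

#' Cartesian to spherical angles
#'
#' Inverse of [sph_to_cart()]. `theta` is returned in `[0, 180]` and `phi`
#' in `[0, 360)`; callers that need the measurement quarter sphere map the
#' result through the degeneracy rules themselves.
#'
#' @param v Unit vector (length 3) or matrix with one vector per row.
#' @return List with `theta_deg` and `phi_deg`.
#' @export
cart_to_sph <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  th <- acos(clamp(v[, 3], -1, 1))
  ph <- atan2(v[, 2], v[, 1])
  ph <- ph %% (2 * pi)
  list(theta_deg = rad2deg(th), phi_deg = rad2deg(ph))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Great-circle angle between unit vectors, degrees
#' @param u,v Unit vectors (length 3) or matrices of row vectors.
#' @return Angle(s) in `[0, 180]` degrees.
#' @export
angular_distance <- function(u, v) {
  if (is.null(dim(u)) && is.null(dim(v))) {
    return(rad2deg(acos(clamp(sum(u * v), -1, 1))))
  }
  if (is.null(dim(u))) u <- matrix(u, nrow = NROW(v), ncol = 3, byrow = TRUE)
  if (is.null(dim(v))) v <- matrix(v, nrow = NROW(u), ncol = 3, byrow = TRUE)
  rad2deg(acos(clamp(rowSums(u * v), -1, 1)))
}

# Rotation about an arbitrary axis (Rodrigues), angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  a <- unit(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random 3D rotation (via QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Circular mean of angles (degrees) with a given period.
circular_mean <- function(x_deg, period = 360, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x_deg))
  a <- deg2rad(x_deg * 360 / period)
  m <- atan2(sum(w * sin(a)), sum(w * cos(a)))
  (rad2deg(m) * period / 360) %% period
}

# Circular standard deviation (degrees) about the circular mean; for the
# narrow distributions handled here this is the RMS angular deviation.
circular_sd <- function(x_deg, period = 360, w = NULL) {
  if (length(x_deg) < 2) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(x_deg))
  m <- circular_mean(x_deg, period, w)
  d <- (x_deg - m + period / 2) %% period - period / 2
  sqrt(sum(w * d^2) / sum(w))
}

# All permutations of seq_len(n) as rows of a matrix (n <= 7 intended).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }
  do.call(rbind, out)
}
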