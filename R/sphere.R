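#' Gauss-Legendre product quadrature on the unit sphere
#'
#' Nodes are the product of Gauss-Legendre abscissae in \eqn{\cos\theta} and an
#' equally spaced grid in azimuth, so smooth spherical integrands (ODFs,
#' diffusion kernels) are integrated to near machine precision. Weights sum to
#' \eqn{4\pi}.
#'
#' @param n_theta number of polar nodes (Gauss-Legendre in \eqn{\cos\theta})
#' @param n_phi number of azimuthal nodes
#' @return list with `points` (N x 3 unit vectors) and `weights` (length N)
#' @export
sphere_quadrature <- function(n_theta = 64L, n_phi = 128L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  pts <- cbind(st * cos(phi), st * sin(phi), ct)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  list(points = pts, weights = w)
}

#' Near-uniform directions on the sphere or hemisphere
#'
#' Deterministic Fibonacci spiral point set; the hemisphere variant keeps the
#' upper half (z >= 0), as used for diffusion gradient tables where antipodal
#' directions are equivalent.
#'
#' @param n number of directions
#' @param hemisphere logical; restrict to z >= 0
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  if (hemisphere) {
    z <- 1 - i / n          # z in (0, 1)
  } else {
    z <- 1 - 2 * i / n      # z in (-1, 1)
  }
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

# Rotation taking the z-axis onto unit vector mu (any completion of the frame).
rotation_to <- function(mu) {
  mu <- mu / sqrt(sum(mu^2))
  if (abs(mu[3]) > 1 - 1e-12) {
    return(diag(sign(mu[3]), 3) * diag(c(1, sign(mu[3]), 1)))
  }
  ref <- c(0, 0, 1)
  v1 <- ref - mu * sum(ref * mu)
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(
    mu[2] * v1[3] - mu[3] * v1[2],
    mu[3] * v1[1] - mu[1] * v1[3],
    mu[1] * v1[2] - mu[2] * v1[1]
  )
  cbind(v1, v2, mu)
}

# Euler-angle rotation matrix (z-y-z convention); columns form the frame.
euler_frame <- function(theta, phi, psi) {
  cz1 <- cos(phi); sz1 <- sin(phi)
  cy <- cos(theta); sy <- sin(theta)
  cz2 <- cos(psi); sz2 <- sin(psi)
  Rz1 <- matrix(c(cz1, sz1, 0, -sz1, cz1, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz2 <- matrix(c(cz2, sz2, 0, -sz2, cz2, 0, 0, 0, 1), 3, 3)
  Rz1 %*% Ry %*% Rz2
}

#' Real spherical harmonic design matrix (even orders)
#'
#' Orthonormal real basis evaluated at unit vectors, restricted to even degrees
#' l = 0, 2, ..., lmax as appropriate for antipodally symmetric diffusion
#' signals. Column order is (l, m) with m = -l..l.
#'
#' @param dirs N x 3 unit vectors
#' @param lmax maximum (even) harmonic degree
#' @return N x R matrix, R = (lmax+1)(lmax+2)/2
#' @export
sh_basis <- function(dirs, lmax = 4L) {
  stopifnot(lmax %% 2 == 0)
  dirs <- matrix(dirs, ncol = 3)
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  ls <- seq(0, lmax, by = 2)
  ncoef <- sum(2 * ls + 1)
  Y <- matrix(0, n, ncoef)
  col <- 1
  for (l in ls) {
    # pracma::legendre returns P_l^m(x) for m = 0..l (Condon-Shortley phase)
    P <- pracma::legendre(l, ct)
    if (l == 0) P <- matrix(P, nrow = 1)
    for (m in seq(-l, l)) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
      if (m < 0) {
        Y[, col] <- sqrt(2) * nrm * P[am + 1, ] * sin(am * phi)
      } else if (m == 0) {
        Y[, col] <- nrm * P[1, ]
      } else {
        Y[, col] <- sqrt(2) * nrm * P[am + 1, ] * cos(am * phi)
      }
      col <- col + 1
    }
  }
  attr(Y, "l_index") <- unlist(lapply(ls, function(l) rep(l, 2 * l + 1)))
  Y
}

# Degree labels for the columns of sh_basis(lmax)
sh_degrees <- function(lmax) unlist(lapply(seq(0, lmax, 2), function(l) rep(l, 2 * l + 1)))
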