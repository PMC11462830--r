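# Design-matrix helpers for log-linear tensor fits ---------------------------

# 6 unique second-order monomials: g' D g = m6 . d6
d6_monomials <- function(g) {
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

d6_to_matrix <- function(d) {
  matrix(c(d[1], d[4] / 1, d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
}

# 15 unique fourth-order monomials with multiplicities, ordered as:
# xxxx yyyy zzzz  xxxy xxxz xyyy yyyz xzzz yzzz  xxyy xxzz yyzz  xxyz xyyz xyzz
w15_monomials <- function(g) {
  x <- g[, 1]; y <- g[, 2]; z <- g[, 3]
  cbind(x^4, y^4, z^4,
        4 * x^3 * y, 4 * x^3 * z, 4 * x * y^3, 4 * y^3 * z, 4 * x * z^3, 4 * y * z^3,
        6 * x^2 * y^2, 6 * x^2 * z^2, 6 * y^2 * z^2,
        12 * x^2 * y * z, 12 * x * y^2 * z, 12 * x * y * z^2)
}

check_signals <- function(signals) {
  n_bad <- sum(signals <= 0)
  if (n_bad > 0) {
    warning(sprintf("%d non-positive signal(s) clamped before log transform", n_bad))
    signals <- pmax(signals, 1e-8 * max(signals, 1e-12))
  }
  list(signals = signals, n_clamped = n_bad)
}

# Two-step weighted linear least squares on log-signals (weights = squared
# predicted signals from an OLS pre-pass).
wlls <- function(X, logs) {
  beta0 <- qr.coef(qr(X), logs)
  w <- exp(2 * as.vector(X %*% beta0))
  Xw <- X * sqrt(w)
  qr.coef(qr(Xw), logs * sqrt(w))
}

#' Fit the diffusion tensor (DTI)
#'
#' Weighted linear least squares on log-signals using the b0 measurements and
#' the low-b shell only (b <= `b_max`, default 1.25 ms/um^2 = 1250 s/mm^2),
#' the convention for tensor fits from two-shell DKI acquisitions.
#'
#' @param signals numeric signal vector (one voxel)
#' @param scheme a `dwi_scheme`
#' @param b_max largest b-value (ms/um^2) used in the fit
#' @return object of class `dti_fit`: tensor `D` (um^2/ms), sorted
#'   `eigenvalues`, `eigenvectors`, `lnS0`, `n_clamped`
#' @export
fit_dti <- function(signals, scheme, b_max = 1.3) {
  use <- scheme$bval <= b_max
  b <- scheme$bval[use]
  if (sum(b > 0) < 6 || length(b) < 7) stop("need >= 7 measurements including a nonzero shell at b <= b_max")
  cs <- check_signals(signals[use])
  X <- cbind(1, -b * d6_monomials(scheme$bvec[use, , drop = FALSE]))
  beta <- wlls(X, log(cs$signals))
  D <- d6_to_matrix(beta[-1])
  e <- eigen(D, symmetric = TRUE)
  structure(list(D = D, eigenvalues = e$values, eigenvectors = e$vectors,
                 lnS0 = beta[1], n_clamped = cs$n_clamped),
            class = "dti_fit")
}

#' Scalar DTI metrics
#'
#' Fractional anisotropy, mean/axial/radial diffusivity from the sorted
#' eigenvalues:
#' \deqn{FA = \sqrt{\frac{(\lambda_1-\lambda_2)^2 + (\lambda_1-\lambda_3)^2 +
#'   (\lambda_2-\lambda_3)^2}{2(\lambda_1^2+\lambda_2^2+\lambda_3^2)}}}
#' \eqn{MD = (\lambda_1+\lambda_2+\lambda_3)/3}, \eqn{AD = \lambda_1},
#' \eqn{RD = (\lambda_2+\lambda_3)/2}. FA of an all-zero tensor is defined
#' as 0.
#'
#' @param fit a `dti_fit` (or a numeric vector of 3 eigenvalues)
#' @return named list FA, MD, AD, RD
#' @export
dti_metrics <- function(fit) {
  l <- if (inherits(fit, "dti_fit")) fit$eigenvalues else sort(fit, decreasing = TRUE)
  ss <- sum(l^2)
  fa <- if (ss == 0) 0 else {
    sqrt(((l[1] - l[2])^2 + (l[1] - l[3])^2 + (l[2] - l[3])^2) / (2 * ss))
  }
  list(FA = fa, MD = mean(l), AD = l[1], RD = (l[2] + l[3]) / 2)
}

#' @export
print.dti_fit <- function(x, ...) {
  m <- dti_metrics(x)
  cat(sprintf("DTI fit: FA %.3f, MD %.3f um^2/ms (lambda %.3f/%.3f/%.3f)\n",
              m$FA, m$MD, x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3]))
  invisible(x)
}

#' @export
coef.dti_fit <- function(object, ...) {
  c(lnS0 = unname(object$lnS0),
    Dxx = object$D[1, 1], Dyy = object$D[2, 2], Dzz = object$D[3, 3],
    Dxy = object$D[1, 2], Dxz = object$D[1, 3], Dyz = object$D[2, 3])
}

#' Fit the diffusion kurtosis model (DKI)
#'
#' Weighted linear least squares in the 22-parameter log-linear model
#' \deqn{\ln S = \ln S_0 - b\, g^T D g + \tfrac{1}{6} b^2 \sum g_ig_jg_kg_l \tilde W_{ijkl}}
#' with \eqn{\tilde W = \bar D^2 W}; the kurtosis tensor W is recovered after
#' the fit by dividing by the squared mean diffusivity. Requires at least two
#' nonzero shells.
#'
#' @param signals numeric signal vector (one voxel)
#' @param scheme a `dwi_scheme`
#' @return object of class `dki_fit`: `D`, `W15` (15 unique elements of W,
#'   dimensionless), `MD`, eigensystem of D, `lnS0`, `n_clamped`
#' @export
fit_dki <- function(signals, scheme) {
  b <- scheme$bval
  shells <- unique(round(b[b > 1e-9], 6))
  if (length(shells) < 2) stop("kurtosis fit requires at least two nonzero shells")
  if (length(b) < 22) stop("kurtosis fit requires >= 22 measurements")
  cs <- check_signals(signals)
  g <- scheme$bvec
  X <- cbind(1, -b * d6_monomials(g), (b^2 / 6) * w15_monomials(g))
  beta <- wlls(X, log(cs$signals))
  D <- d6_to_matrix(beta[2:7])
  md <- mean(diag(D))
  W15 <- beta[8:22] / md^2
  e <- eigen(D, symmetric = TRUE)
  structure(list(D = D, W15 = W15, MD = md, eigenvalues = e$values,
                 eigenvectors = e$vectors, lnS0 = beta[1],
                 n_clamped = cs$n_clamped),
            class = "dki_fit")
}

#' Directional apparent diffusivity and kurtosis
#'
#' For directions g: \eqn{D_{app}(g) = g^T D g} and
#' \eqn{K_{app}(g) = \bar D^2 \, W_{app}(g) / D_{app}(g)^2} with
#' \eqn{W_{app} = \sum g_ig_jg_kg_l W_{ijkl}}.
#'
#' @param fit a `dki_fit`
#' @param dirs N x 3 unit vectors
#' @param k_clip optional c(min, max) soft clip for K_app; clipped values are
#'   counted in the `n_clipped` attribute
#' @return data frame with D_app, K_app
#' @export
directional_kurtosis <- function(fit, dirs, k_clip = c(-3 / 7, 10)) {
  dirs <- matrix(dirs, ncol = 3)
  d_app <- rowSums((dirs %*% fit$D) * dirs)
  w_app <- as.vector(w15_monomials(dirs) %*% fit$W15)
  k_app <- fit$MD^2 * w_app / d_app^2
  n_clip <- 0L
  if (!is.null(k_clip)) {
    n_clip <- sum(k_app < k_clip[1] | k_app > k_clip[2])
    k_app <- clamp(k_app, k_clip[1], k_clip[2])
  }
  out <- data.frame(D_app = d_app, K_app = k_app)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Scalar kurtosis metrics
#'
#' MK is the mean of the directional kurtosis over a dense near-uniform
#' direction set; AK is the kurtosis along the principal eigenvector; RK is
#' the mean over directions in the plane perpendicular to it. A degenerate
#' tensor (lambda1 ~ lambda2) is flagged and the tie broken by the fixed
#' eigenvector ordering of the symmetric eigendecomposition.
#'
#' @param fit a `dki_fit`
#' @param n_dirs number of directions for the MK average (>= 100)
#' @param n_radial number of in-plane directions for RK
#' @return named list AK, MK, RK (+ attribute `degenerate`)
#' @export
dki_metrics <- function(fit, n_dirs = 250L, n_radial = 64L) {
  stopifnot(n_dirs >= 100L)
  dirs <- fibonacci_sphere(n_dirs)
  mk <- mean(directional_kurtosis(fit, dirs)$K_app)
  e1 <- fit$eigenvectors[, 1]
  degen <- abs(fit$eigenvalues[1] - fit$eigenvalues[2]) <
    1e-6 * max(abs(fit$eigenvalues[1]), 1e-12)
  ak <- directional_kurtosis(fit, matrix(e1, 1))$K_app
  perp <- rotation_to(e1)[, 1:2]
  ang <- 2 * pi * (seq_len(n_radial) - 1) / n_radial
  rdirs <- cbind(cos(ang), sin(ang)) %*% t(perp)
  rk <- mean(directional_kurtosis(fit, rdirs)$K_app)
  out <- list(AK = unname(ak), MK = mk, RK = rk)
  attr(out, "degenerate") <- degen
  out
}

#' WMTI axonal water fraction from maximal kurtosis
#'
#' \eqn{AWF = K_{max} / (K_{max} + 3)} with \eqn{K_{max}} the largest
#' directional kurtosis over a dense direction set. Negative \eqn{K_{max}}
#' (possible under noise) is clamped to 0 and flagged.
#'
#' @param fit a `dki_fit`
#' @param n_dirs directions over which the maximum is taken
#' @return AWF in [0, 1) with attribute `clamped`
#' @export
awf_from_kurtosis <- function(fit, n_dirs = 250L) {
  k_max <- max(directional_kurtosis(fit, fibonacci_sphere(n_dirs))$K_app)
  clamped <- k_max < 0
  if (clamped) k_max <- 0
  structure(k_max / (k_max + 3), clamped = clamped)
}

#' Kurtosis signal model along one direction
#'
#' \eqn{S(b)/S(0) = \exp(-b D_{app} + \tfrac16 b^2 D_{app}^2 K_{app})}.
#'
#' @param b b-value(s) in ms/um^2
#' @param D_app apparent diffusivity (um^2/ms)
#' @param K_app apparent kurtosis
#' @return signal ratio(s)
#' @export
kurtosis_signal <- function(b, D_app, K_app) {
  exp(-b * D_app + (b^2 * D_app^2 * K_app) / 6)
}

#' Closed-form per-direction kurtosis solve
#'
#' With measurements at b = 0, b1, b2 along one direction the log-signal model
#' \eqn{\ln S(b) = \ln S_0 - b D + \tfrac16 b^2 D^2 K} has an exact solution;
#' used as an oracle for the tensor fits and available for quick QA.
#'
#' @param signals length-3 signal vector at `bvals`
#' @param bvals length-3 b-values (ms/um^2), first must be 0
#' @return list D_app, K_app, lnS0
#' @export
solve_direction_kurtosis <- function(signals, bvals) {
  stopifnot(length(signals) == 3, length(bvals) == 3, bvals[1] == 0)
  y <- log(signals / signals[1])[-1]
  b <- bvals[-1]
  # y = -b D + (1/6) b^2 V ; V = D^2 K
  A <- cbind(-b, b^2 / 6)
  sol <- solve(A, y)
  list(D_app = sol[1], K_app = sol[2] / sol[1]^2, lnS0 = log(signals[1]))
}
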