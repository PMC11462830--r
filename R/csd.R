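# Cached hemisphere mesh with projective-metric neighbor graph, used for the
# nonnegativity constraint grid, peak finding and lobe watershed.
csd_mesh <- function(n = 1000L, k = 8L) {
  key <- sprintf("mesh_%d_%d", n, k)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  pts <- fibonacci_sphere(n, hemisphere = TRUE)
  adot <- abs(pts %*% t(pts))
  nb <- t(apply(adot, 1, function(row) order(row, decreasing = TRUE)[2:(k + 1)]))
  mesh <- list(points = pts, neighbors = nb, weight = 4 * pi / n)
  .quad_cache[[key]] <- mesh
  mesh
}

#' Estimate the single-fiber response function
#'
#' Selects voxels whose DTI fractional anisotropy exceeds a threshold, rotates
#' each voxel's high-b-shell signal into the frame of its principal
#' eigenvector, and fits an axially symmetric (zonal, m = 0) spherical-harmonic
#' profile. The averaged zonal coefficients are the deconvolution response; the
#' stacked aligned samples are kept for inspection, and the relative spread of
#' per-voxel coefficients is a bias diagnostic (large spread means non-single-
#' fiber voxels contaminated the estimate).
#'
#' @param signal_matrix voxels x measurements signal matrix
#' @param scheme a `dwi_scheme`
#' @param fa_threshold minimum FA for inclusion
#' @param shell_b b-value (ms/um^2) of the shell to deconvolve (default: the
#'   highest shell)
#' @param lmax_zonal zonal fit order
#' @return object of class `csd_response`: `rho` (zonal SH coefficients),
#'   `shell_b`, `samples`, `dispersion`, `flags`
#' @export
estimate_response <- function(signal_matrix, scheme, fa_threshold = 0.7,
                              shell_b = NULL, lmax_zonal = 8L) {
  signal_matrix <- matrix(signal_matrix, ncol = length(scheme))
  if (is.null(shell_b)) shell_b <- max(scheme$shells$b)
  sel <- abs(scheme$bval - shell_b) < 1e-6
  fits <- apply(signal_matrix, 1, function(s) {
    ft <- fit_dti(s, scheme)
    list(fa = dti_metrics(ft)$FA, e1 = ft$eigenvectors[, 1])
  })
  fa <- vapply(fits, `[[`, 0, "fa")
  keep <- which(fa >= fa_threshold)
  if (length(keep) == 0) stop("no voxel exceeds the FA threshold")
  ls <- seq(0, lmax_zonal, 2)
  zonal_design <- function(ct) {
    vapply(ls, function(l) {
      P <- pracma::legendre(l, ct)
      if (l == 0) P <- matrix(P, nrow = 1)
      sqrt((2 * l + 1) / (4 * pi)) * P[1, ]
    }, numeric(length(ct)))
  }
  coefs <- NULL
  samples <- NULL
  for (v in keep) {
    ct <- abs(as.vector(scheme$bvec[sel, , drop = FALSE] %*% fits[[v]]$e1))
    Z <- zonal_design(pmin(1, ct))
    cf <- qr.coef(qr(Z), signal_matrix[v, sel])
    coefs <- rbind(coefs, cf)
    samples <- rbind(samples, data.frame(cos_theta = ct, signal = signal_matrix[v, sel]))
  }
  rho <- colMeans(coefs)
  disp <- if (nrow(coefs) > 1) {
    mean(apply(coefs, 2, stats::sd)) / max(abs(rho))
  } else 0
  flags <- if (disp > 0.1) "high per-voxel coefficient dispersion (mixed voxels?)" else character(0)
  structure(list(rho = rho, ls = ls, shell_b = shell_b, samples = samples,
                 dispersion = disp, n_voxels = length(keep), flags = flags),
            class = "csd_response")
}

#' Constrained spherical deconvolution of the high-b shell
#'
#' Solves for the fiber ODF in the even spherical-harmonic basis by iteratively
#' reweighted least squares with a soft nonnegativity constraint on a dense
#' hemisphere grid (amplitudes below a fraction of the initial mean are
#' penalized), until the active constraint set stabilizes or the iteration cap
#' is reached.
#'
#' @param signals one voxel's signal vector
#' @param scheme a `dwi_scheme`
#' @param response a `csd_response`
#' @param lmax fODF harmonic order (default 4; 25 directions support it)
#' @param lambda constraint weight
#' @param tau relative amplitude threshold defining "negative"
#' @param max_iter iteration cap
#' @return object of class `fodf`: SH coefficients `coefs`, `lmax`, `peaks`
#'   (direction, amplitude), `converged`, `flags`
#' @export
csd_fit <- function(signals, scheme, response, lmax = 4L, lambda = 1,
                    tau = 0.1, max_iter = 50L) {
  sel <- abs(scheme$bval - response$shell_b) < 1e-6
  s <- signals[sel]
  dirs <- scheme$bvec[sel, , drop = FALSE]
  Y <- sh_basis(dirs, lmax)
  ldeg <- sh_degrees(lmax)
  rho <- response$rho[match(ldeg, response$ls)]
  rl <- rho * sqrt(4 * pi / (2 * ldeg + 1))
  A <- Y * rep(rl, each = nrow(Y))

  mesh <- csd_mesh()
  B <- sh_basis(mesh$points, lmax)

  f <- qr.coef(qr(A), s)                      # unconstrained start
  amp0 <- B %*% f
  thr <- tau * mean(pmax(amp0, 0))
  scale_A <- mean(colSums(A^2))
  active_prev <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    amp <- as.vector(B %*% f)
    active <- which(amp < thr)
    if (!is.null(active_prev) && identical(active, active_prev)) {
      converged <- TRUE
      break
    }
    active_prev <- active
    if (length(active) == 0) { converged <- TRUE; break }
    Bn <- B[active, , drop = FALSE]
    M <- crossprod(A) + lambda^2 * (scale_A / nrow(Bn)) * crossprod(Bn)
    f <- solve(M, crossprod(A, s))
  }
  flags <- if (!converged) "constraint set did not stabilize (last iterate returned)" else character(0)
  peaks <- fodf_peaks(f, lmax, mesh)
  structure(list(coefs = as.vector(f), lmax = lmax, peaks = peaks,
                 converged = converged, flags = flags),
            class = "fodf")
}

# Local maxima of the fODF on the mesh, refined by Nelder-Mead over (theta,phi).
fodf_peaks <- function(coefs, lmax, mesh = csd_mesh(), rel_threshold = 0.2) {
  amp <- as.vector(sh_basis(mesh$points, lmax) %*% coefs)
  is_peak <- vapply(seq_along(amp), function(i) {
    amp[i] > 0 && all(amp[i] >= amp[mesh$neighbors[i, ]])
  }, TRUE)
  if (!any(is_peak)) return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0), amplitude = numeric(0)))
  idx <- which(is_peak)
  refine <- function(p0) {
    th0 <- acos(clamp(p0[3], -1, 1)); ph0 <- atan2(p0[2], p0[1])
    neg_amp <- function(a) {
      d <- c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))
      -as.vector(sh_basis(matrix(d, 1), lmax) %*% coefs)
    }
    opt <- stats::optim(c(th0, ph0), neg_amp, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-10))
    d <- c(sin(opt$par[1]) * cos(opt$par[2]), sin(opt$par[1]) * sin(opt$par[2]), cos(opt$par[1]))
    if (d[3] < 0) d <- -d
    c(d, -opt$value)
  }
  pk <- t(vapply(idx, function(i) refine(mesh$points[i, ]), numeric(4)))
  # deduplicate (projective): keep strongest within 10 degrees
  ord <- order(pk[, 4], decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(vapply(kept, function(j) abs(sum(pk[i, 1:3] * pk[j, 1:3])) < cos(10 * pi / 180), TRUE))) {
      kept <- c(kept, i)
    }
  }
  pk <- pk[kept, , drop = FALSE]
  pk <- pk[pk[, 4] >= rel_threshold * max(pk[, 4]), , drop = FALSE]
  data.frame(x = pk[, 1], y = pk[, 2], z = pk[, 3], amplitude = pk[, 4])
}

#' @export
print.fodf <- function(x, ...) {
  cat(sprintf("fODF (lmax %d): %d peak(s), total integral %.4g\n",
              x$lmax, nrow(x$peaks), x$coefs[1] * sqrt(4 * pi)))
  invisible(x)
}

#' Apparent fiber density metrics from a fiber ODF
#'
#' `afd_total` is the fODF's integral over the sphere (l = 0 coefficient times
#' \eqn{\sqrt{4\pi}}). Lobes are segmented by steepest-ascent watershed on a
#' dense hemisphere mesh (antipodal pairs merged); `afd_max` is the largest
#' per-lobe integral and `afd_sum` the sum of lobe integrals over lobes whose
#' peak amplitude exceeds `peak_threshold` times the global peak.
#'
#' @param fodf a `fodf` (or a numeric vector of SH coefficients)
#' @param peak_threshold relative lobe-inclusion threshold
#' @param lmax harmonic order when `fodf` is a raw coefficient vector
#' @return named list afd_max, afd_sum, afd_total (+ `lobes` data frame)
#' @export
afd_metrics <- function(fodf, peak_threshold = 0.1, lmax = NULL) {
  if (inherits(fodf, "fodf")) {
    coefs <- fodf$coefs; lmax <- fodf$lmax
  } else {
    coefs <- as.numeric(fodf)
    if (is.null(lmax)) lmax <- c(0, 2, 4, 6, 8)[match(length(coefs), c(1, 6, 15, 28, 45))]
  }
  afd_total <- coefs[1] * sqrt(4 * pi)
  mesh <- csd_mesh()
  amp <- as.vector(sh_basis(mesh$points, lmax) %*% coefs)
  pos <- pmax(amp, 0)
  if (all(pos == 0)) {
    return(list(afd_max = 0, afd_sum = 0, afd_total = afd_total,
                lobes = data.frame(peak = numeric(0), integral = numeric(0))))
  }
  # steepest ascent: each vertex points to its best-improving neighbor
  up <- vapply(seq_along(amp), function(i) {
    nb <- mesh$neighbors[i, ]
    j <- nb[which.max(amp[nb])]
    if (amp[j] > amp[i]) j else i
  }, 1L)
  root <- seq_along(amp)
  for (rep_i in 1:50) {
    nxt <- up[root]
    if (identical(nxt, root)) break
    root <- nxt
  }
  lab <- match(root, unique(root))
  lobes <- do.call(rbind, lapply(seq_len(max(lab)), function(k) {
    sel <- lab == k & pos > 0
    data.frame(peak = if (any(sel)) max(amp[sel]) else 0,
               integral = sum(pos[sel]) * mesh$weight)
  }))
  lobes <- lobes[lobes$integral > 0, , drop = FALSE]
  if (nrow(lobes) == 0) {
    return(list(afd_max = 0, afd_sum = 0, afd_total = afd_total, lobes = lobes))
  }
  keep <- lobes$peak >= peak_threshold * max(lobes$peak)
  list(afd_max = max(lobes$integral[keep]),
       afd_sum = sum(lobes$integral[keep]),
       afd_total = afd_total,
       lobes = lobes)
}
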