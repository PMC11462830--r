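# NODDI intrinsic diffusivities (um^2/ms), fixed by convention
.noddi_dpar <- 1.7
.noddi_diso <- 3.0

#' Orientation dispersion index
#'
#' \eqn{ODI = (2/\pi) \arctan(1/\kappa)}; 1 for a uniform ODF (kappa = 0), 0
#' in the parallel-fiber limit.
#'
#' @param kappa Watson concentration (>= 0)
#' @return ODI in [0, 1]
#' @export
odi_from_kappa <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  (2 / pi) * atan2(1, kappa)
}

#' @rdname odi_from_kappa
#' @param odi ODI in (0, 1]
#' @export
kappa_from_odi <- function(odi) {
  stopifnot(all(odi > 0), all(odi <= 1))
  1 / tan(pi / 2 * odi)
}

#' Dispersion anisotropy index of a Bingham ODF
#'
#' Documented convention: \eqn{DAI = (2/\pi)\arctan((\kappa_1-\kappa_2)/\kappa_2)}
#' for \eqn{\kappa_2 > 0}; 1 when \eqn{\kappa_2 = 0 < \kappa_1}; 0 when
#' \eqn{\kappa_1 = \kappa_2}.
#'
#' @param kappa1,kappa2 Bingham concentrations, kappa1 >= kappa2 >= 0
#' @return DAI in [0, 1]
#' @export
dai_from_kappas <- function(kappa1, kappa2) {
  stopifnot(kappa1 >= kappa2, kappa2 >= 0)
  if (kappa1 == kappa2) return(0)
  if (kappa2 == 0) return(1)
  (2 / pi) * atan((kappa1 - kappa2) / kappa2)
}

#' Ground truth satisfying the Watson-NODDI coupling
#'
#' Builds a [microstructure_truth()] under the NODDI assumptions: fixed
#' intrinsic diffusivity 1.7 um^2/ms, free water 3.0 um^2/ms, and
#' tortuosity-coupled extra-neurite perpendicular diffusivity
#' \eqn{D_{e\perp} = d_\parallel (1 - V_{ic})}. Signals simulated from it are
#' exactly representable by the Watson (or Bingham) fit.
#'
#' @param Vic intracellular fraction of the non-isotropic part
#' @param Viso isotropic (free-water) fraction
#' @param odi orientation dispersion index (Watson)
#' @param mu principal orientation
#' @param kappa1,kappa2 Bingham concentrations (override `odi` when given)
#' @param frame optional Bingham frame
#' @return a `microstructure_truth`
#' @export
noddi_truth <- function(Vic, Viso, odi = 0.3, mu = c(0, 0, 1),
                        kappa1 = NULL, kappa2 = NULL, frame = NULL) {
  if (is.null(kappa1)) {
    kappa1 <- kappa2 <- kappa_from_odi(odi)
    kind <- "watson"
  } else {
    if (is.null(kappa2)) kappa2 <- kappa1
    kind <- "bingham"
  }
  microstructure_truth(
    f_intra = (1 - Viso) * Vic, f_iso = Viso,
    Da = .noddi_dpar, De_par = .noddi_dpar,
    De_perp = .noddi_dpar * (1 - Vic), d_iso = .noddi_diso,
    odf_kind = kind, kappa1 = kappa1, kappa2 = kappa2, mu = mu, frame = frame
  )
}

# ---- cached per-scheme precomputations -------------------------------------

scheme_key <- function(scheme, tag) {
  paste(tag, length(scheme$bval), signif(sum(scheme$bval), 10),
        signif(sum(scheme$bvec^2 * seq_along(scheme$bvec)), 10), sep = "_")
}

noddi_precomp <- function(scheme, quad = fit_quad()) {
  key <- scheme_key(scheme, "noddi")
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  b <- scheme$bval
  C2 <- (scheme$bvec %*% t(quad$points))^2
  Eic <- exp(sweep(C2, 1, -b * .noddi_dpar, `*`))
  pc <- list(quad = quad, b = b, C2 = C2, Eic = Eic,
             ball = exp(-b * .noddi_diso))
  .quad_cache[[key]] <- pc
  pc
}

# Watson ODF quadrature weights (normalized, already including quad weights)
watson_wq <- function(mu, kappa, quad) {
  w <- exp(kappa * (as.vector(quad$points %*% mu)^2 - 1)) * quad$weights
  w / sum(w)
}

bingham_wq <- function(frame, kappa1, kappa2, quad) {
  w <- exp(-kappa1 * as.vector(quad$points %*% frame[, 2])^2 -
             kappa2 * as.vector(quad$points %*% frame[, 3])^2) * quad$weights
  w / sum(w)
}

# Deterministic initialization grid over (Vic, ODI, orientation, Viso); the
# predicted-signal matrix is cached per scheme so multi-voxel fits pay the
# grid cost once.
noddi_grid <- function(scheme, grid_n = c(8L, 8L, 30L, 4L)) {
  key <- scheme_key(scheme, paste0("noddi_grid_", paste(grid_n, collapse = "x")))
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  pc <- noddi_precomp(scheme)
  quad <- pc$quad
  vic_g <- seq(0.1, 0.9, length.out = grid_n[1])
  odi_g <- seq(0.04, 0.9, length.out = grid_n[2])
  mu_g <- fibonacci_sphere(grid_n[3], hemisphere = TRUE)
  viso_g <- c(0, 0.2, 0.45, 0.7)[seq_len(grid_n[4])]

  kap_g <- kappa_from_odi(odi_g)
  W <- matrix(0, length(quad$weights), length(kap_g) * nrow(mu_g))
  col <- 1
  for (kap in kap_g) for (im in seq_len(nrow(mu_g))) {
    W[, col] <- watson_wq(mu_g[im, ], kap, quad)
    col <- col + 1
  }
  Aic <- pc$Eic %*% W                    # n_meas x (n_odi*n_mu)
  pred <- NULL
  pars <- NULL
  for (iv in seq_along(vic_g)) {
    vic <- vic_g[iv]
    Aec <- exp(-pc$b * .noddi_dpar * (1 - vic)) * ((pc$Eic^vic) %*% W)
    for (iw in seq_along(viso_g)) {
      P <- (1 - viso_g[iw]) * (vic * Aic + (1 - vic) * Aec) + viso_g[iw] * pc$ball
      pred <- cbind(pred, P)
      pars <- rbind(pars, data.frame(
        vic = vic, viso = viso_g[iw],
        kappa = rep(kap_g, each = nrow(mu_g)),
        imu = rep(seq_len(nrow(mu_g)), times = length(kap_g))))
    }
  }
  g <- list(pred = pred, pars = pars, mu_g = mu_g)
  .quad_cache[[key]] <- g
  g
}

# Predicted S/S0 for the (tortuosity-coupled) NODDI signal model given ODF
# quadrature weights.
noddi_predict <- function(pc, wq, Vic, Viso) {
  a_ic <- as.vector(pc$Eic %*% wq)
  scale_ec <- exp(-pc$b * .noddi_dpar * (1 - Vic))
  a_ec <- scale_ec * as.vector((pc$Eic^Vic) %*% wq)
  (1 - Viso) * (Vic * a_ic + (1 - Vic) * a_ec) + Viso * pc$ball
}

# Profile out S0 and return the residual sum of squares.
profile_sse <- function(s, pred) {
  s0 <- sum(s * pred) / sum(pred^2)
  list(s0 = s0, sse = sum((s - s0 * pred)^2))
}

#' Fit the Watson-NODDI model to one voxel
#'
#' Maximum-likelihood fit (Gaussian objective on magnitudes) of the
#' three-compartment NODDI signal model with fixed intrinsic diffusivities
#' (1.7 / 3.0 um^2/ms) and tortuosity-coupled extra-cellular perpendicular
#' diffusivity. Initialization is a deterministic coarse grid over
#' (Vic, ODI, orientation, Viso) followed by Nelder-Mead refinement with a
#' small restart budget; the fit is fully deterministic.
#'
#' @param signals numeric signal vector (one voxel)
#' @param scheme a `dwi_scheme` with two nonzero shells
#' @param grid_n list-free tuning: c(n_vic, n_odi, n_mu, n_viso)
#' @param restarts Nelder-Mead restart budget
#' @return object of class `noddi_fit`: `Vic`, `Viso`, `kappa`, `ODI`, `mu`,
#'   `S0`, `sse`, `converged`, `flags`
#' @export
fit_noddi_watson <- function(signals, scheme, grid_n = c(8L, 8L, 30L, 4L),
                             restarts = 3L) {
  if (sum(scheme$shells$b > 1e-9) < 2) stop("need two nonzero shells")
  pc <- noddi_precomp(scheme)
  quad <- pc$quad
  grid <- noddi_grid(scheme, grid_n)

  # vectorized grid search with S0 profiled out per candidate
  nrm <- colSums(grid$pred^2)
  cross <- as.vector(crossprod(grid$pred, signals))
  sse <- sum(signals^2) - cross^2 / nrm
  ibest <- which.min(sse)
  best <- list(sse = sse[ibest], vic = grid$pars$vic[ibest],
               viso = grid$pars$viso[ibest], kappa = grid$pars$kappa[ibest],
               mu = grid$mu_g[grid$pars$imu[ibest], ],
               s0 = cross[ibest] / nrm[ibest])

  obj <- function(p) {
    vic <- stats::plogis(p[1]); viso <- stats::plogis(p[2])
    kap <- exp(p[3])
    mu <- c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
    wq <- watson_wq(mu, kap, quad)
    profile_sse(signals, noddi_predict(pc, wq, vic, viso))$sse
  }
  mu0 <- best$mu
  p <- c(stats::qlogis(clamp(best$vic, 0.01, 0.99)),
         stats::qlogis(clamp(best$viso, 0.01, 0.99)),
         log(max(best$kappa, 1e-3)),
         acos(clamp(mu0[3], -1, 1)), atan2(mu0[2], mu0[1]))
  converged <- FALSE
  for (r in seq_len(restarts)) {
    opt <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-10))
    p <- opt$par
    if (opt$convergence == 0) { converged <- TRUE; break }
  }
  vic <- stats::plogis(p[1]); viso <- stats::plogis(p[2]); kap <- exp(p[3])
  mu <- c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
  if (mu[3] < 0) mu <- -mu
  wq <- watson_wq(mu, kap, quad)
  pr <- profile_sse(signals, noddi_predict(pc, wq, vic, viso))
  flags <- character(0)
  if (!converged) flags <- c(flags, "non-convergence (best candidate returned)")
  if (viso >= 0.95) flags <- c(flags, "icvf_unidentifiable")
  structure(list(Vic = unname(vic), Viso = unname(viso), kappa = unname(kap),
                 ODI = unname(odi_from_kappa(kap)), mu = unname(mu), S0 = pr$s0,
                 sse = pr$sse, converged = converged, flags = flags),
            class = "noddi_fit")
}

#' @export
print.noddi_fit <- function(x, ...) {
  cat(sprintf("Watson-NODDI fit: ICVF %.3f, ODI %.3f, Viso %.3f%s\n",
              x$Vic, x$ODI, x$Viso,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]") else ""))
  invisible(x)
}

#' @export
coef.noddi_fit <- function(object, ...) {
  c(ICVF = object$Vic, ODI = object$ODI, Viso = object$Viso, kappa = object$kappa)
}

#' Fit the Bingham-NODDI model to one voxel
#'
#' As [fit_noddi_watson()] but with a Bingham ODF
#' (\eqn{\kappa_1 \ge \kappa_2 \ge 0} about an orthonormal frame), allowing
#' anisotropic orientation dispersion (fanning). Initialized from the Watson
#' fit (kappa1 = kappa2) and refined by Nelder-Mead over the full frame.
#' Emits Bin-ICVF, Bin-ODI = (2/pi) arctan(1/sqrt(kappa1 kappa2)) and the
#' dispersion anisotropy index [dai_from_kappas()].
#'
#' @inheritParams fit_noddi_watson
#' @param watson optional precomputed `noddi_fit` used for initialization
#' @return object of class `bingham_fit`
#' @export
fit_noddi_bingham <- function(signals, scheme, watson = NULL, restarts = 3L) {
  pc <- noddi_precomp(scheme)
  quad <- pc$quad
  if (is.null(watson)) watson <- fit_noddi_watson(signals, scheme)

  obj <- function(p) {
    vic <- stats::plogis(p[1]); viso <- stats::plogis(p[2])
    k2 <- exp(p[3]); k1 <- k2 + exp(p[4])
    fr <- euler_frame(p[5], p[6], p[7])
    wq <- bingham_wq(fr, k1, k2, quad)
    profile_sse(signals, noddi_predict(pc, wq, vic, viso))$sse
  }
  mu <- watson$mu
  p <- c(stats::qlogis(clamp(watson$Vic, 0.01, 0.99)),
         stats::qlogis(clamp(watson$Viso, 0.01, 0.99)),
         log(max(watson$kappa, 1e-3)), log(0.05),
         acos(clamp(mu[3], -1, 1)), atan2(mu[2], mu[1]), 0)
  converged <- FALSE
  for (r in seq_len(restarts)) {
    opt <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = 1500, reltol = 1e-10))
    p <- opt$par
    if (opt$convergence == 0) { converged <- TRUE; break }
  }
  vic <- stats::plogis(p[1]); viso <- stats::plogis(p[2])
  k2 <- exp(p[3]); k1 <- k2 + exp(p[4])
  fr <- euler_frame(p[5], p[6], p[7])
  wq <- bingham_wq(fr, k1, k2, quad)
  pr <- profile_sse(signals, noddi_predict(pc, wq, vic, viso))
  flags <- character(0)
  if (!converged) flags <- c(flags, "non-convergence (best candidate returned)")
  if (viso >= 0.95) flags <- c(flags, "icvf_unidentifiable")
  structure(list(Vic = unname(vic), Viso = unname(viso),
                 kappa1 = unname(k1), kappa2 = unname(k2),
                 frame = fr,
                 Bin_ODI = unname(odi_from_kappa(sqrt(k1 * k2))),
                 DAI = unname(dai_from_kappas(k1, k2)),
                 S0 = pr$s0, sse = pr$sse, converged = converged, flags = flags),
            class = "bingham_fit")
}

#' @export
print.bingham_fit <- function(x, ...) {
  cat(sprintf("Bingham-NODDI fit: Bin-ICVF %.3f, Bin-ODI %.3f, DAI %.3f, Viso %.3f\n",
              x$Vic, x$Bin_ODI, x$DAI, x$Viso))
  invisible(x)
}

#' @export
coef.bingham_fit <- function(object, ...) {
  c(Bin_ICVF = object$Vic, Bin_ODI = object$Bin_ODI, DAI = object$DAI,
    Viso = object$Viso, kappa1 = object$kappa1, kappa2 = object$kappa2)
}
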