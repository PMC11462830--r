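#' Watson and Bingham orientation distribution functions
#'
#' Axially symmetric Watson density \eqn{W(n) \propto \exp(\kappa (n\cdot\mu)^2)}
#' and the Bingham generalization
#' \eqn{B(n) \propto \exp(-\kappa_1 (n\cdot e_2)^2 - \kappa_2 (n\cdot e_3)^2)}
#' with principal axis \eqn{e_1} and \eqn{\kappa_1 \ge \kappa_2 \ge 0}; with
#' \eqn{\kappa_1 = \kappa_2 = \kappa} the Bingham density reduces to the Watson
#' density with concentration \eqn{\kappa}. Normalization constants are
#' computed by spherical Gauss-Legendre quadrature so that the density
#' integrates to 1 over the sphere.
#'
#' @param dirs N x 3 unit vectors at which to evaluate the density
#' @param mu principal orientation (unit 3-vector)
#' @param kappa,kappa1,kappa2 concentration parameters (>= 0)
#' @param frame 3 x 3 rotation whose columns are (e1, e2, e3); for
#'   `bingham_odf` overrides `mu`
#' @param quad quadrature from [sphere_quadrature()] used for normalization
#' @return density values (1/steradian)
#' @export
watson_odf <- function(dirs, mu, kappa, quad = default_quad()) {
  dirs <- matrix(dirs, ncol = 3)
  mu <- mu / sqrt(sum(mu^2))
  # normalize exponent to max 0 for numerical safety
  lognum <- kappa * (as.vector(dirs %*% mu)^2 - 1)
  z <- sum(quad$weights * exp(kappa * (as.vector(quad$points %*% mu)^2 - 1)))
  exp(lognum) / z
}

#' @rdname watson_odf
#' @export
bingham_odf <- function(dirs, frame, kappa1, kappa2, quad = default_quad()) {
  stopifnot(kappa1 >= kappa2, kappa2 >= 0)
  dirs <- matrix(dirs, ncol = 3)
  e2 <- frame[, 2]; e3 <- frame[, 3]
  f <- function(p) exp(-kappa1 * as.vector(p %*% e2)^2 - kappa2 * as.vector(p %*% e3)^2)
  z <- sum(quad$weights * f(quad$points))
  f(dirs) / z
}

# Package-level cached quadratures (simulation-grade and fitting-grade).
.quad_cache <- new.env(parent = emptyenv())

#' @export
#' @rdname watson_odf
default_quad <- function() {
  if (is.null(.quad_cache$sim)) .quad_cache$sim <- sphere_quadrature(64L, 128L)
  .quad_cache$sim
}

fit_quad <- function() {
  if (is.null(.quad_cache$fit)) .quad_cache$fit <- sphere_quadrature(32L, 64L)
  .quad_cache$fit
}

#' Ground-truth microstructure for one voxel
#'
#' Three-compartment tissue model: an intra-neurite "stick" (zero perpendicular
#' diffusivity), an extra-neurite axially symmetric Gaussian (zeppelin) with
#' independent parallel/perpendicular diffusivities, and isotropic free water.
#' The stick and zeppelin share an orientation distribution (delta, Watson or
#' Bingham). Signal fractions are absolute: intra + extra + iso = 1 with
#' extra = 1 - f_intra - f_iso.
#'
#' @param f_intra intra-neurite signal fraction in [0,1]
#' @param f_iso free-water fraction in [0,1]; f_intra + f_iso <= 1
#' @param Da intra-neurite parallel diffusivity (um^2/ms)
#' @param De_par,De_perp extra-neurite diffusivities (um^2/ms)
#' @param d_iso free-water diffusivity (um^2/ms)
#' @param odf_kind "delta", "watson" or "bingham"
#' @param kappa1,kappa2 concentrations (kappa1 >= kappa2; Watson uses kappa1)
#' @param mu principal orientation
#' @param frame optional full frame for Bingham (columns e1,e2,e3)
#' @param S0 non-diffusion-weighted signal
#' @return object of class `microstructure_truth`
#' @export
microstructure_truth <- function(f_intra = 0.5, f_iso = 0.1, Da = 1.7,
                                 De_par = 1.5, De_perp = 0.6, d_iso = 3.0,
                                 odf_kind = c("watson", "bingham", "delta"),
                                 kappa1 = 4, kappa2 = kappa1,
                                 mu = c(0, 0, 1), frame = NULL, S0 = 1) {
  odf_kind <- match.arg(odf_kind)
  if (f_intra < 0 || f_iso < 0 || f_intra + f_iso > 1 + 1e-12) {
    stop("signal fractions must be nonnegative with f_intra + f_iso <= 1")
  }
  nrm <- sqrt(sum(mu^2))
  if (abs(nrm - 1) > 1e-6) stop("mu must be a unit vector")
  mu <- mu / nrm
  if (is.null(frame)) frame <- rotation_to(mu)[, c(3, 1, 2)]  # e1 = mu
  structure(list(f_intra = f_intra, f_iso = f_iso, Da = Da, De_par = De_par,
                 De_perp = De_perp, d_iso = d_iso, odf_kind = odf_kind,
                 kappa1 = kappa1, kappa2 = kappa2, mu = mu, frame = frame,
                 S0 = S0),
            class = "microstructure_truth")
}

#' Forward-simulate the diffusion signal for one voxel
#'
#' The stick and zeppelin kernels are convolved with the voxel's ODF by
#' spherical quadrature; the free-water ball is isotropic. At b = 0 the signal
#' equals S0 exactly for every parameter setting.
#'
#' @param truth a [microstructure_truth()]
#' @param scheme a `dwi_scheme`
#' @param quad quadrature used for the ODF convolution
#' @return numeric signal vector, one value per measurement
#' @export
simulate_signal <- function(truth, scheme, quad = default_quad()) {
  stopifnot(inherits(truth, "microstructure_truth"), inherits(scheme, "dwi_scheme"))
  b <- scheme$bval
  g <- scheme$bvec
  f_ex <- 1 - truth$f_intra - truth$f_iso

  stick <- function(cos2, bb) exp(-bb * truth$Da * cos2)
  zepp <- function(cos2, bb) exp(-bb * (truth$De_perp + (truth$De_par - truth$De_perp) * cos2))

  n <- length(b)
  s <- numeric(n)
  if (truth$odf_kind == "delta") {
    c2 <- as.vector(g %*% truth$mu)^2
    a_ic <- stick(c2, b)
    a_ec <- zepp(c2, b)
  } else {
    w <- if (truth$odf_kind == "watson") {
      watson_odf(quad$points, truth$mu, truth$kappa1, quad)
    } else {
      bingham_odf(quad$points, truth$frame, truth$kappa1, truth$kappa2, quad)
    }
    ww <- w * quad$weights
    C2 <- (g %*% t(quad$points))^2        # n_meas x n_quad
    a_ic <- a_ec <- numeric(n)
    for (i in seq_len(n)) {
      if (b[i] == 0) { a_ic[i] <- a_ec[i] <- 1; next }
      a_ic[i] <- sum(exp(-b[i] * truth$Da * C2[i, ]) * ww)
      a_ec[i] <- sum(exp(-b[i] * (truth$De_perp +
                                    (truth$De_par - truth$De_perp) * C2[i, ])) * ww)
    }
  }
  a_iso <- exp(-b * truth$d_iso)
  s <- truth$S0 * (truth$f_intra * a_ic + f_ex * a_ec + truth$f_iso * a_iso)
  s[b == 0] <- truth$S0
  s
}

#' Add Rician noise to a signal vector
#'
#' Magnitude of (signal + N(0, sigma)) + i N(0, sigma) with sigma = S0/snr,
#' the noise model of magnitude MR images. `snr = Inf` returns the input.
#'
#' @param signal noise-free signal
#' @param snr b0 signal-to-noise ratio (> 0)
#' @param seed integer seed; the global RNG state is left untouched
#' @param S0 reference signal defining sigma (default max of `signal`)
#' @return noisy signal vector
#' @export
add_rician_noise <- function(signal, snr, seed = NULL, S0 = max(signal)) {
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive")
  if (is.infinite(snr)) return(signal)
  sigma <- S0 / snr
  noisy <- with_seed(seed, {
    re <- signal + stats::rnorm(length(signal), 0, sigma)
    im <- stats::rnorm(length(signal), 0, sigma)
    sqrt(re^2 + im^2)
  })
  noisy
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-stage seed derivation from a global seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Per-metric cohort effect table
#'
#' Group means and standard deviations for each of the 21 ROI metrics under
#' two presets. The `study-like` preset sets the recurrence-group shift so the
#' standardized effect d = sqrt(2) * qnorm(AUC) reproduces each metric's
#' reported single-feature AUC, with the reported direction of change
#' (recurrence higher AFD/AWF/FA/kurtosis/ICVF/De_par/f; lower AD/MD/RD/
#' De_perp/fw; null effects for ODI, Bin-ODI, DAI, Da). The `null` preset sets
#' all effects to zero.
#'
#' @param preset "study-like" or "null"
#' @return data frame with columns metric, mean_nonrec, mean_rec, sd
#' @export
cohort_effect_table <- function(preset = c("study-like", "null")) {
  preset <- match.arg(preset)
  # metric, non-recurrence mean, SD, reported AUC (NA = non-significant), sign
  spec <- rbind(
    data.frame(metric = "AFD_max",   m = 0.35, s = 0.10, auc = 0.805, dir = +1),
    data.frame(metric = "AFD_sum",   m = 0.50, s = 0.12, auc = 0.722, dir = +1),
    data.frame(metric = "AFD_total", m = 0.60, s = 0.15, auc = 0.774, dir = +1),
    data.frame(metric = "AWF",       m = 0.25, s = 0.07, auc = 0.703, dir = +1),
    data.frame(metric = "AD",        m = 1.70, s = 0.25, auc = 0.682, dir = -1),
    data.frame(metric = "MD",        m = 1.40, s = 0.20, auc = 0.744, dir = -1),
    data.frame(metric = "RD",        m = 1.30, s = 0.20, auc = 0.762, dir = -1),
    data.frame(metric = "FA",        m = 0.25, s = 0.08, auc = 0.732, dir = +1),
    data.frame(metric = "AK",        m = 0.50, s = 0.10, auc = 0.736, dir = +1),
    data.frame(metric = "MK",        m = 0.55, s = 0.12, auc = 0.767, dir = +1),
    data.frame(metric = "RK",        m = 0.60, s = 0.15, auc = 0.744, dir = +1),
    data.frame(metric = "Bin_ICVF",  m = 0.35, s = 0.10, auc = 0.751, dir = +1),
    data.frame(metric = "Bin_ODI",   m = 0.35, s = 0.12, auc = NA,    dir = 0),
    data.frame(metric = "DAI",       m = 0.30, s = 0.10, auc = NA,    dir = 0),
    data.frame(metric = "ICVF",      m = 0.35, s = 0.10, auc = 0.750, dir = +1),
    data.frame(metric = "ODI",       m = 0.35, s = 0.12, auc = NA,    dir = 0),
    data.frame(metric = "Da",        m = 2.00, s = 0.30, auc = NA,    dir = 0),
    data.frame(metric = "De_par",    m = 1.60, s = 0.30, auc = 0.624, dir = +1),
    data.frame(metric = "De_perp",   m = 0.90, s = 0.20, auc = 0.885, dir = -1),
    data.frame(metric = "f",         m = 0.30, s = 0.10, auc = 0.683, dir = +1),
    data.frame(metric = "fw",        m = 0.25, s = 0.10, auc = 0.830, dir = -1)
  )
  d <- ifelse(is.na(spec$auc), 0, sqrt(2) * stats::qnorm(spec$auc)) * spec$dir
  if (preset == "null") d <- rep(0, nrow(spec))
  data.frame(metric = spec$metric,
             mean_nonrec = spec$m,
             mean_rec = spec$m + d * spec$s,
             sd = spec$s)
}

#' Simulate a two-group patient cohort
#'
#' Fast path (`level = "features"`): per-patient ROI metric values are drawn
#' independently from the per-group normal distributions of the effect table -
#' this is the input the statistics and OPLS-DA stages consume. Signal-level
#' path (`level = "signals"`): each patient gets a small 4D volume with tumor
#' and contralateral ROIs whose voxel signals are simulated from
#' microstructure ground truth mapped from the effect table, for end-to-end
#' runs through the fitting stages.
#'
#' @param n_per_group integer pair (non-recurrence, recurrence); defaults to
#'   the study's 25/23
#' @param preset effect-table preset, see [cohort_effect_table()]
#' @param snr b0 SNR for signal-level simulation (Inf = noise-free)
#' @param seed integer seed
#' @param level "features" or "signals"
#' @param scheme acquisition scheme for signal-level simulation
#' @return list with `clinical` (data frame: patient, group, age, gender),
#'   `features` (data frame of 21 metrics; features level) or `datasets` +
#'   `rois` (signals level), and `effects` (the effect table used)
#' @export
make_cohort <- function(n_per_group = c(25L, 23L),
                        preset = c("study-like", "null"),
                        snr = 30, seed = 1L,
                        level = c("features", "signals"),
                        scheme = study_scheme()) {
  preset <- match.arg(preset)
  level <- match.arg(level)
  eff <- cohort_effect_table(preset)
  if (any(eff$sd <= 0)) stop("effect table SDs must be positive")
  n <- sum(n_per_group)
  group <- rep(c("non-recurrence", "recurrence"), n_per_group)

  clinical <- with_seed(derive_seed(seed, "clinical"), data.frame(
    patient = sprintf("P%03d", seq_len(n)),
    group = group,
    age = round(stats::rnorm(n, mean = ifelse(group == "recurrence", 43.2, 40.2), sd = 12)),
    gender = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))

  out <- list(clinical = clinical, effects = eff)
  if (level == "features") {
    feats <- with_seed(derive_seed(seed, "features"), {
      m <- sapply(seq_len(nrow(eff)), function(k) {
        mu <- ifelse(group == "recurrence", eff$mean_rec[k], eff$mean_nonrec[k])
        stats::rnorm(n, mu, eff$sd[k])
      })
      colnames(m) <- eff$metric
      as.data.frame(m)
    })
    out$features <- cbind(clinical[c("patient", "group")], feats)
  } else {
    out$datasets <- with_seed(derive_seed(seed, "signals"), {
      lapply(seq_len(n), function(i) {
        simulate_patient_volume(group[i], preset, snr, scheme)
      })
    })
    out$rois <- attr(out$datasets[[1]], "rois")
  }
  out
}

# One small patient volume: 4 x 2 x 1 grid, first 2x2 patch tumor tissue,
# second patch contralateral-like reference tissue.
simulate_patient_volume <- function(group, preset, snr, scheme) {
  rec <- group == "recurrence"
  # microstructure shifts consistent with the effect directions
  f_intra <- clamp(stats::rnorm(1, if (rec) 0.45 else 0.32, 0.04), 0.05, 0.8)
  f_iso <- clamp(stats::rnorm(1, if (rec) 0.12 else 0.22, 0.04), 0, 0.5)
  kap <- clamp(stats::rnorm(1, 3.5, 0.5), 0.5, 16)
  de_perp <- clamp(stats::rnorm(1, if (rec) 0.55 else 0.8, 0.08), 0.1, 1.4)
  truth_tumor <- microstructure_truth(f_intra = f_intra, f_iso = f_iso,
                                      Da = 1.9, De_par = 1.5, De_perp = de_perp,
                                      odf_kind = "watson", kappa1 = kap,
                                      mu = c(0, 0, 1))
  truth_ref <- microstructure_truth(f_intra = 0.55, f_iso = 0.05, Da = 2.0,
                                    De_par = 1.6, De_perp = 0.5,
                                    odf_kind = "watson", kappa1 = 8,
                                    mu = c(1, 0, 0))
  dims <- c(4L, 2L, 1L)
  sig <- array(0, dim = c(dims, length(scheme)))
  tum <- array(FALSE, dims); tum[1:2, , 1] <- TRUE
  ref <- array(FALSE, dims); ref[3:4, , 1] <- TRUE
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    tr <- if (tum[i, j, 1]) truth_tumor else truth_ref
    s <- simulate_signal(tr, scheme)
    sig[i, j, 1, ] <- add_rician_noise(s, snr, seed = NULL, S0 = tr$S0)
  }
  ds <- structure(list(signal = sig, scheme = scheme,
                       voxel_size = c(1.875, 1.875, 3), affine = diag(4)),
                  class = "dwi_dataset")
  attr(ds, "rois") <- structure(list(tumor_rois = list(tum), reference_roi = ref,
                                     diameter_mm = 6), class = "roi_set")
  ds
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
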