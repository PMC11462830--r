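test_that("DTI recovers a known tensor and its scalar metrics", {
  sch <- test_scheme()
  td <- microstructure_truth(f_intra = 0, f_iso = 0, De_par = 1.7, De_perp = 0.3,
                             odf_kind = "delta", mu = c(0, 0, 1))
  fit <- fit_dti(simulate_signal(td, sch), sch)
  expect_equal(fit$eigenvalues, c(1.7, 0.3, 0.3), tolerance = 1e-6)

  m <- dti_metrics(fit)
  expect_equal(m$FA, 0.7990, tolerance = 1e-4)
  expect_equal(m$MD, 0.7667, tolerance = 1e-4)
  expect_equal(m$RD, 0.3, tolerance = 1e-6)

  # isotropic signals
  iso <- exp(-sch$bval * 1.0)
  mi <- dti_metrics(fit_dti(iso, sch))
  expect_equal(mi$FA, 0, tolerance = 1e-9)
  expect_equal(mi$MD, 1.0, tolerance = 1e-9)

  # closed-form limits of the metric formulas
  expect_equal(dti_metrics(c(1.3, 1.3, 1.3))$FA, 0)
  expect_equal(dti_metrics(c(2, 0, 0))$FA, 1)
  expect_equal(dti_metrics(c(0, 0, 0))$FA, 0)

  expect_error(fit_dti(rep(1, 51), build_scheme(rep(0, 51), matrix(0, 51, 3))),
               "nonzero shell")
})

test_that("FA is rotation invariant and AD >= MD >= RD", {
  sch <- test_scheme()
  set.seed(4)
  base <- microstructure_truth(f_intra = 0, f_iso = 0, De_par = 1.7,
                               De_perp = 0.4, odf_kind = "delta", mu = c(0, 0, 1))
  fa0 <- dti_metrics(fit_dti(simulate_signal(base, sch), sch))$FA
  for (i in 1:5) {
    R <- random_rotation()
    mu <- as.vector(R %*% c(0, 0, 1))
    tr <- microstructure_truth(f_intra = 0, f_iso = 0, De_par = 1.7,
                               De_perp = 0.4, odf_kind = "delta", mu = mu)
    m <- dti_metrics(fit_dti(simulate_signal(tr, sch), sch))
    expect_equal(m$FA, fa0, tolerance = 1e-8)
    expect_true(m$AD >= m$MD && m$MD >= m$RD)
    expect_equal(m$MD, mean(fit_dti(simulate_signal(tr, sch), sch)$eigenvalues))
  }
})

test_that("DKI recovers all 21 tensor parameters from noise-free signals", {
  sch <- test_scheme()
  set.seed(6)
  R <- random_rotation()
  D <- R %*% diag(c(1.5, 0.8, 0.4)) %*% t(R)
  W15 <- rnorm(15, 0.2, 0.3)
  md <- mean(diag(D))
  g <- sch$bvec; b <- sch$bval
  d6 <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  m6 <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
              2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  x <- g[, 1]; y <- g[, 2]; z <- g[, 3]
  m15 <- cbind(x^4, y^4, z^4, 4 * x^3 * y, 4 * x^3 * z, 4 * x * y^3, 4 * y^3 * z,
               4 * x * z^3, 4 * y * z^3, 6 * x^2 * y^2, 6 * x^2 * z^2,
               6 * y^2 * z^2, 12 * x^2 * y * z, 12 * x * y^2 * z, 12 * x * y * z^2)
  s <- exp(log(500) - b * (m6 %*% d6) + (b^2 / 6) * md^2 * (m15 %*% W15))

  fit <- fit_dki(s, sch)
  expect_lt(max(abs(fit$D - D)), 1e-6)
  expect_lt(max(abs(fit$W15 - W15)), 1e-6)

  expect_error(fit_dki(s[sch$bval <= 1.3], build_scheme(
    1000 * sch$bval[sch$bval <= 1.3], sch$bvec[sch$bval <= 1.3, ])), "two nonzero")
})

test_that("per-direction kurtosis solve and signal model are mutually inverse", {
  b <- c(0, 1.25, 2.5)
  s <- kurtosis_signal(b, 1.0, 1.0)
  sol <- solve_direction_kurtosis(s, b)
  expect_equal(sol$D_app, 1.0, tolerance = 1e-12)
  expect_equal(sol$K_app, 1.0, tolerance = 1e-12)
  # Gaussian limit: K = 0 reduces to the monoexponential
  expect_equal(kurtosis_signal(b, 1.0, 0), exp(-b))
})

test_that("kurtosis metrics: isotropy, dense-average oracle, monotonicity", {
  sch <- test_scheme()
  # isotropic D and W with K_app = 0.8 everywhere: W_iiii = 3c, W_iijj = c
  md <- 1.0; k <- 0.8; c0 <- k / 3
  W15 <- c(rep(3 * c0, 3), rep(0, 6), rep(c0, 3), rep(0, 3))
  s <- exp(-sch$bval * md + (sch$bval^2 / 6) * md^2 * k)
  fit <- fit_dki(s, sch)
  km <- dki_metrics(fit)
  expect_equal(km$AK, 0.8, tolerance = 1e-6)
  expect_equal(km$MK, 0.8, tolerance = 1e-6)
  expect_equal(km$RK, 0.8, tolerance = 1e-6)
  expect_lt(max(abs(fit$W15 - W15)), 1e-6)

  # W = 0 gives zero kurtosis metrics
  s0 <- exp(-sch$bval * md)
  km0 <- dki_metrics(fit_dki(s0, sch))
  expect_lt(max(abs(unlist(km0))), 1e-8)

  # anisotropic fit: MK within 2% of a 10,000-direction brute-force average
  tr <- microstructure_truth(f_intra = 0.5, f_iso = 0.1, Da = 2.2,
                             De_par = 1.5, De_perp = 0.6,
                             odf_kind = "watson", kappa1 = 4)
  fita <- fit_dki(simulate_signal(tr, sch), sch)
  mk_dense <- mean(directional_kurtosis(fita, fibonacci_sphere(10000))$K_app)
  expect_equal(dki_metrics(fita)$MK, mk_dense, tolerance = 0.02)

  # MK non-decreasing in a positive perturbation of any single W element
  mk0 <- dki_metrics(fita)$MK
  for (j in c(1, 10, 12)) {
    f2 <- fita
    f2$W15[j] <- f2$W15[j] + 0.05
    expect_gte(dki_metrics(f2)$MK, mk0 - 1e-10)
  }
})

test_that("AWF follows the maximal-kurtosis map with clamping", {
  sch <- test_scheme()
  # K_app = 3 isotropic: AWF = 0.5
  s <- exp(-sch$bval + (sch$bval^2 / 6) * 3)
  expect_equal(as.numeric(awf_from_kurtosis(fit_dki(s, sch))), 0.5,
               tolerance = 1e-6)
  # K = 0: AWF = 0
  expect_equal(as.numeric(awf_from_kurtosis(fit_dki(exp(-sch$bval), sch))), 0,
               tolerance = 1e-6)
  # K = 1.2: AWF = 1.2/4.2
  s12 <- exp(-sch$bval + (sch$bval^2 / 6) * 1.2)
  expect_equal(as.numeric(awf_from_kurtosis(fit_dki(s12, sch))), 1.2 / 4.2,
               tolerance = 1e-6)
  # negative kurtosis is clamped and flagged
  sneg <- exp(-sch$bval - (sch$bval^2 / 6) * 0.5)
  awf <- awf_from_kurtosis(fit_dki(sneg, sch))
  expect_equal(as.numeric(awf), 0)
  expect_true(attr(awf, "clamped"))
})
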