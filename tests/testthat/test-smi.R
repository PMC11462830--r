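test_that("rotational invariants: isotropy, rotation invariance, truncation", {
  sch <- test_scheme()
  # isotropic signal has no l = 2, 4 power
  iso <- exp(-sch$bval * 1.1)
  inv <- decompose_invariants(iso, sch)
  expect_lt(max(inv$inv$S2), 1e-12)
  expect_lt(max(inv$inv$S4), 1e-12)
  expect_equal(inv$inv$S0, exp(-c(1.25, 2.5) * 1.1), tolerance = 1e-12)

  # rotating directions and signal together leaves invariants unchanged
  tr <- microstructure_truth(odf_kind = "watson", kappa1 = 5, mu = c(0, 0, 1))
  s <- simulate_signal(tr, sch)
  i0 <- decompose_invariants(s, sch)
  set.seed(3)
  R <- random_rotation()
  sch_r <- build_scheme(sch$bval * 1000, sch$bvec %*% t(R))
  tr_r <- microstructure_truth(odf_kind = "watson", kappa1 = 5,
                               mu = as.vector(R %*% c(0, 0, 1)))
  i1 <- decompose_invariants(simulate_signal(tr_r, sch_r), sch_r)
  expect_lt(max(abs(as.matrix(i0$inv) - as.matrix(i1$inv))), 1e-6)

  # lmax exceeding the direction support errors
  expect_error(decompose_invariants(s, sch, lmax = 6), "directions per shell")
})

test_that("forward invariants match numerical quadrature of the kernel-ODF integral", {
  # oracle: simulate the convolution signal by dense spherical quadrature,
  # project onto SH by quadrature, and collapse to invariants
  kap <- 6
  al <- watson_alignment(kap)
  sch <- test_scheme()
  tr <- microstructure_truth(f_intra = 0.5, f_iso = 0.07, Da = 2.1,
                             De_par = 1.4, De_perp = 0.5,
                             odf_kind = "watson", kappa1 = kap,
                             mu = c(0.1, 0.5, sqrt(1 - 0.01 - 0.25)))
  fwd <- smi_forward(f = 0.5, Da = 2.1, De_par = 1.4, De_perp = 0.5, fw = 0.07,
                     p2 = al$p2, p4 = al$p4)
  for (i in 1:2) {
    b <- c(1.25, 2.5)[i]
    sig_fn <- function(dirs) {
      sub <- build_scheme(rep(b * 1000, nrow(dirs)), dirs)
      simulate_signal(tr, sub)
    }
    inv_q <- quad_invariants(sig_fn, lmax = 4)
    expect_equal(unname(fwd$S0[i]), inv_q[1], tolerance = 1e-4)
    expect_equal(unname(fwd$S2[i]), inv_q[2], tolerance = 1e-4)
    expect_equal(unname(fwd$S4[i]), inv_q[3], tolerance = 1e-4)
  }

  # trivial kernel limits
  z <- smi_forward(f = 0, Da = 2, De_par = 1, De_perp = 1, fw = 0, p2 = 0.5)
  expect_equal(z$S0, exp(-c(1.25, 2.5)), tolerance = 1e-10)
  expect_lt(max(z$S2), 1e-10)
  p0 <- smi_forward(f = 0.6, Da = 2, De_par = 1.5, De_perp = 0.4, fw = 0, p2 = 0)
  expect_lt(max(p0$S2), 1e-12)
})

test_that("delta-ODF phantom invariants match the closed-form kernel ratios", {
  sch <- test_scheme()
  tr <- microstructure_truth(f_intra = 1, f_iso = 0, Da = 2.0,
                             odf_kind = "delta", mu = c(0.2, -0.4, sqrt(0.8)))
  inv <- decompose_invariants(simulate_signal(tr, sch), sch)
  fwd <- smi_forward(f = 1, Da = 2.0, De_par = 2.0, De_perp = 0, fw = 0,
                     p2 = 1, p4 = 1)
  # SH truncation at lmax = 4 from 25 directions limits the agreement
  expect_equal(inv$inv$S2 / inv$inv$S0, fwd$S2 / fwd$S0, tolerance = 0.02)
})

test_that("standard-model estimation recovers the canonical truth and limits", {
  est <- smi_test_estimator()
  fwd <- smi_forward(f = 0.5, Da = 2.2, De_par = 1.5, De_perp = 0.6,
                     fw = 0.05, p2 = 0.7)
  inv <- structure(list(inv = fwd, s0 = 1, lmax = 4), class = "rot_invariants")
  fit <- fit_smi(inv, estimator = est)
  expect_lt(abs(fit$f - 0.5), 0.05)
  expect_lt(abs(fit$fw - 0.05), 0.05)
  expect_lt(abs(fit$Da - 2.2), 0.2)
  expect_lt(abs(fit$De_par - 1.5), 0.2)
  expect_lt(abs(fit$De_perp - 0.6), 0.2)

  # same invariants, same estimator: identical output
  expect_identical(coef(fit), coef(fit_smi(inv, estimator = est)))

  # pure free water
  water <- data.frame(b = c(1.25, 2.5), S0 = exp(-3 * c(1.25, 2.5)),
                      S2 = 0, S4 = 0)
  fw_fit <- fit_smi(structure(list(inv = water, s0 = 1, lmax = 4),
                              class = "rot_invariants"), estimator = est)
  expect_gte(fw_fit$fw, 0.9)

  # identifiability diagnostic is reported per parameter
  expect_named(fit$r2, c("f", "Da", "De_par", "De_perp", "fw", "p2"))
  expect_true(all(fit$r2 <= 1))
})

test_that("estimation works end-to-end from simulated signals", {
  est <- smi_test_estimator()
  sch <- test_scheme()
  tab <- watson_alignment(seq(0.5, 30, 0.25))
  kap <- stats::approx(tab$p2, seq(0.5, 30, 0.25), xout = 0.7)$y
  tr <- microstructure_truth(f_intra = 0.5, f_iso = 0.05, Da = 2.2,
                             De_par = 1.5, De_perp = 0.6,
                             odf_kind = "watson", kappa1 = kap,
                             mu = c(0.2, -0.4, sqrt(0.8)))
  fit <- fit_smi(decompose_invariants(simulate_signal(tr, sch), sch),
                 estimator = est)
  # SH truncation adds to the estimator tolerance here
  expect_lt(abs(fit$f - 0.5), 0.06)
  expect_lt(abs(fit$Da - 2.2), 0.2)
  expect_lt(abs(fit$fw - 0.05), 0.06)
})
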