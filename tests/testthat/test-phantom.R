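test_that("single-compartment limits of the simulator are exact", {
  sch <- test_scheme()
  # pure free water: S/S0 = exp(-b d_iso) in every direction
  tw <- microstructure_truth(f_intra = 0, f_iso = 1, d_iso = 3.0)
  s <- simulate_signal(tw, sch)
  expect_equal(s, exp(-sch$bval * 3.0), tolerance = 1e-12)

  # b = 0 returns S0 for any truth
  tr <- microstructure_truth(S0 = 123.4)
  expect_equal(simulate_signal(tr, sch)[sch$b0], 123.4)

  # stick perpendicular to the gradient keeps full signal at any b
  mu <- c(0, 0, 1)
  td <- microstructure_truth(f_intra = 1, f_iso = 0, Da = 2.0,
                             odf_kind = "delta", mu = mu)
  perp <- abs(as.vector(sch$bvec %*% mu)) < 1e-12
  s <- simulate_signal(td, sch)
  expect_equal(s[perp & !sch$b0], rep(1, sum(perp & !sch$b0)), tolerance = 1e-12)
})

test_that("highly concentrated Watson ODF converges to the parallel-fiber kernel", {
  sch <- test_scheme()
  tw <- microstructure_truth(odf_kind = "watson", kappa1 = 300, mu = c(0, 0, 1))
  td <- microstructure_truth(odf_kind = "delta", mu = c(0, 0, 1))
  expect_lt(max(abs(simulate_signal(tw, sch) - simulate_signal(td, sch))), 5e-3)
})

test_that("ODF densities integrate to one under an independent finer quadrature", {
  q_fine <- sphere_quadrature(128L, 256L)
  for (k in c(0, 1, 4, 16, 64)) {
    w <- watson_odf(q_fine$points, c(0.3, -0.5, sqrt(1 - 0.09 - 0.25)), k)
    expect_equal(sum(w * q_fine$weights), 1, tolerance = 1e-4)
  }
  fr <- diag(3)
  for (ks in list(c(0, 0), c(4, 1), c(16, 2))) {
    w <- bingham_odf(q_fine$points, fr, ks[1], ks[2])
    expect_equal(sum(w * q_fine$weights), 1, tolerance = 1e-4)
  }
})

test_that("noise-free signals are positive and bounded by S0", {
  sch <- test_scheme()
  set.seed(11)
  for (i in 1:10) {
    fi <- runif(1, 0, 0.8); fo <- runif(1, 0, 1 - fi)
    da <- runif(1, 1, 3)
    dep <- runif(1, 0.5, da); dpp <- runif(1, 0, dep)
    tr <- microstructure_truth(f_intra = fi, f_iso = fo, Da = da,
                               De_par = dep, De_perp = dpp,
                               odf_kind = "watson", kappa1 = runif(1, 0, 20))
    s <- simulate_signal(tr, sch)
    expect_true(all(s > 0))
    expect_true(all(s <= 1 + 1e-12))
  }
})

test_that("Rician noise has the Rayleigh mean at zero signal and is seed-stable", {
  # zero signal, sigma = 1: mean over draws ~ sigma * sqrt(pi/2)
  z <- add_rician_noise(rep(0, 20000), snr = 1, seed = 5, S0 = 1)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.02)

  s <- exp(-seq(0, 2, length.out = 30))
  expect_identical(add_rician_noise(s, 20, seed = 9),
                   add_rician_noise(s, 20, seed = 9))
  expect_identical(add_rician_noise(s, Inf), s)
  expect_error(add_rician_noise(s, -2), "positive")
})

test_that("study-like cohort reproduces the reported effect directions", {
  eff <- cohort_effect_table("study-like")
  higher <- c("AFD_max", "AFD_sum", "AFD_total", "AWF", "FA", "AK", "MK", "RK",
              "Bin_ICVF", "ICVF", "De_par", "f")
  lower <- c("AD", "MD", "RD", "De_perp", "fw")
  nulls <- c("Bin_ODI", "DAI", "ODI", "Da")
  d <- eff$mean_rec - eff$mean_nonrec
  names(d) <- eff$metric
  expect_true(all(d[higher] > 0))
  expect_true(all(d[lower] < 0))
  expect_true(all(d[nulls] == 0))

  # large-n sample means respect the directions for all 17 shifted metrics
  ch <- make_cohort(n_per_group = c(400L, 400L), preset = "study-like", seed = 2)
  f <- ch$features
  dm <- vapply(eff$metric, function(m) {
    mean(f[[m]][f$group == "recurrence"]) - mean(f[[m]][f$group == "non-recurrence"])
  }, 0)
  expect_true(all(sign(dm[c(higher, lower)]) == sign(d[c(higher, lower)])))
})

test_that("null-preset cohorts are exchangeable and seeds are reproducible", {
  ch1 <- make_cohort(preset = "null", seed = 31)
  ch2 <- make_cohort(preset = "null", seed = 31)
  expect_identical(ch1$features, ch2$features)
  eff <- cohort_effect_table("null")
  expect_true(all(eff$mean_rec == eff$mean_nonrec))

  # zero effects: single-feature AUCs hover around 0.5
  big <- make_cohort(n_per_group = c(300L, 300L), preset = "null", seed = 17)
  rt <- cohort_roc_table(big$features)
  expect_lt(max(abs(rt$auc - 0.5)), 0.08)
})
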