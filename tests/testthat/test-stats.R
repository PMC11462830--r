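test_that("ROI aggregation averages ROI means with optional normalization", {
  dims <- c(8, 8, 1)
  m1 <- array(FALSE, dims); m1[1:2, 1:2, 1] <- TRUE
  m2 <- array(FALSE, dims); m2[5:6, 1:2, 1] <- TRUE
  ref <- array(FALSE, dims); ref[7:8, 7:8, 1] <- TRUE
  rois <- structure(list(tumor_rois = list(m1, m2), reference_roi = ref,
                         diameter_mm = 6), class = "roi_set")
  vol <- array(0, dims)
  vol[m1] <- 1; vol[m2] <- 3; vol[ref] <- 2
  row <- aggregate_roi(list(x = vol), rois, normalize = TRUE)
  expect_equal(row$x, 2)        # equal-weight mean of ROI means 1 and 3
  expect_equal(row$x_norm, 1)   # 2 / reference mean 2

  # a constant map aggregates to the constant
  cm <- array(2.5, dims)
  expect_equal(aggregate_roi(list(x = cm), rois)$x, 2.5)

  # voxel-pooled mean would differ when ROI sizes differ; document by example
  m3 <- array(FALSE, dims); m3[1:4, 5:8, 1] <- TRUE  # 16 voxels
  rois2 <- structure(list(tumor_rois = list(m1, m3), reference_roi = NULL,
                          diameter_mm = 6), class = "roi_set")
  vol2 <- array(0, dims); vol2[m1] <- 1; vol2[m3] <- 3
  expect_equal(aggregate_roi(list(x = vol2), rois2)$x, 2)          # ROI-mean
  expect_equal(mean(vol2[m1 | m3]), (4 * 1 + 16 * 3) / 20)         # pooled

  expect_error(aggregate_roi(list(x = vol[1:4, , , drop = FALSE]), rois), "grids")
})

test_that("group comparison routes by normality and handles edge cases", {
  set.seed(12)
  # identical groups: maximal p
  x <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  r <- compare_groups(x, g)
  expect_gt(r$p, 0.9)

  # constant feature flagged with p = 1
  rc <- compare_groups(rep(1, 10), g)
  expect_equal(rc$p, 1)
  expect_true("constant feature" %in% rc$flags)

  # huge separation: tiny p
  xx <- c(rnorm(25), rnorm(23, 5))
  gg <- rep(c("a", "b"), c(25, 23))
  expect_lt(compare_groups(xx, gg)$p, 1e-6)

  # heavy-tailed data routes to the rank test most of the time
  routes <- replicate(40, {
    y <- c(rt(25, 2), rt(23, 2))
    compare_groups(y, gg)$test
  })
  expect_gt(mean(routes == "Mann-Whitney U"), 0.5)

  expect_error(compare_groups(c(1, 2, 1, 2), rep(c("a", "b"), 2)), "n >= 3")
})

test_that("chi-square matches a brute-force oracle on random R x C tables", {
  set.seed(13)
  for (i in 1:25) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    tab <- matrix(sample(1:20, nr * nc, replace = TRUE), nr, nc)
    got <- chi_square(tab)
    want <- brute_chisq(tab)
    expect_equal(got$statistic, want$stat, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # independence gives statistic 0, p 1
  r0 <- chi_square(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("chi-square reproduces the published clinical table p-values", {
  counts <- clinical_reference_counts()
  expect_equal(round(chi_square(counts$lesion_margin)$p, 2), 0.010, tolerance = 1e-9)
  expect_equal(round(chi_square(counts$grading)$p, 2), 0.020, tolerance = 1e-9)
  expect_equal(sum(counts$grading), 47)  # one unknown-grade record dropped
  expect_equal(round(chi_square(counts$midline_invasion)$p, 3), 0.882)
  expect_equal(round(chi_square(counts$lesion_location)$p, 3), 0.571)
  expect_equal(round(chi_square(counts$lesion_size)$p, 3), 0.154)
})

test_that("ROC analysis equals exhaustive pair counting", {
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  r5 <- roc_analysis(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(r5$auc, 0.5)
  expect_equal(roc_analysis(1:6, c(0, 1, 0, 1, 0, 1))$auc, 6 / 9,
               tolerance = 1e-12)

  set.seed(14)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(1:4, n, replace = TRUE)  # ties likely
    got <- roc_analysis(scores, labels)
    want <- brute_auc(scores, labels)
    expect_equal(got$auc, max(want, 1 - want), tolerance = 1e-12)
    expect_true(got$auc >= 0.5)
    expect_true(got$ci[1] <= got$auc && got$auc <= got$ci[2])
  }
})

test_that("Youden operating point maximizes sensitivity + specificity", {
  scores <- c(0.1, 0.2, 0.35, 0.4, 0.6, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 0, 1, 1, 1)
  r <- roc_analysis(scores, labels)
  # oracle: enumerate every cut
  best_j <- max(vapply(c(-Inf, scores), function(cut) {
    sens <- mean(scores[labels == 1] > cut)
    spec <- mean(scores[labels == 0] <= cut)
    sens + spec - 1
  }, 0))
  expect_equal(r$sensitivity + r$specificity - 1, best_j, tolerance = 1e-12)
})

test_that("paired DeLong comparison behaves at the identity and under power", {
  set.seed(15)
  y <- rep(c(0, 1), each = 100)
  a <- rnorm(200) + 2 * y       # strong feature
  b <- rnorm(200)               # useless feature
  same <- delong_compare(a, a, y)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_lt(delong_compare(a, b, y)$p, 0.01)

  # consistent row permutation leaves the statistic unchanged
  perm <- sample(200)
  z1 <- delong_compare(a, b, y)$statistic
  z2 <- delong_compare(a[perm], b[perm], y[perm])$statistic
  expect_equal(abs(z1), abs(z2), tolerance = 1e-10)
})

test_that("exclusion filter reproduces the patient-flow arithmetic", {
  flow <- clinical_reference_counts()$flow
  n <- flow["candidates"]
  cand <- data.frame(id = seq_len(n))
  crit <- list(
    no_routine_mri = seq_len(n) <= 42,
    incomplete_resection = seq_len(n) > 42 & seq_len(n) <= 45,
    no_postop_mri = seq_len(n) > 45 & seq_len(n) <= 121
  )
  res <- exclusion_filter(cand, crit)
  expect_equal(unname(res$removed), c(42L, 3L, 76L))
  expect_equal(res$n_included, 48L)

  # no flags: identity; all flags: empty
  expect_equal(exclusion_filter(cand, list(x = rep(FALSE, n)))$n_included, as.integer(n))
  expect_equal(exclusion_filter(cand, list(x = rep(TRUE, n)))$n_included, 0L)
})
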