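test_that("with no orthogonal components the model is exactly PLS1", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(8:10, 1); p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rep(c(-1, 1), length.out = n)
    m <- fit_oplsda(X, y, n_ortho = 0)
    o <- nipals_pls1(X, y)
    expect_lt(max(abs(m$t - o$scores)), 1e-8)
    expect_lt(max(abs(abs(m$w) - abs(o$w))), 1e-8)
  }
})

encode_y_test <- function(y) ifelse(as.integer(as.factor(y)) == 1, -1, 1)

test_that("orthogonal scores are orthogonal to predictive scores and to y", {
  set.seed(22)
  X <- matrix(rnorm(30 * 8), 30)
  y <- rep(c(0, 1), 15)
  m <- fit_oplsda(X, y, n_ortho = 2)
  expect_lt(max(abs(crossprod(m$t, m$T_o))), 1e-8)
  expect_lt(max(abs(stats::cor(m$T_o, encode_y_test(y)))), 1e-8)
  expect_equal(sum(m$w^2), 1, tolerance = 1e-12)
})

test_that("fit is equivariant under variable permutation", {
  set.seed(23)
  X <- matrix(rnorm(24 * 6), 24)
  colnames(X) <- paste0("v", 1:6)
  y <- rep(c(0, 1), 12)
  m1 <- fit_oplsda(X, y, n_ortho = 1)
  perm <- c(4, 2, 6, 1, 3, 5)
  m2 <- fit_oplsda(X[, perm], y, n_ortho = 1)
  expect_lt(max(abs(m1$t - m2$t)), 1e-8)
  expect_lt(max(abs(m1$w[perm] - m2$w)), 1e-8)
  expect_equal(m1$vip[perm], m2$vip, tolerance = 1e-10)
})

test_that("VIP has unit mean square, flags informative variables, 1 for copies", {
  set.seed(24)
  # identical copies: all VIP = 1
  base <- rnorm(30)
  Xc <- cbind(base, base, base, base) + 0
  y <- rep(c(0, 1), 15)
  mc <- fit_oplsda(Xc + matrix(rnorm(120, 0, 1e-8), 30), y, n_ortho = 0)
  expect_equal(unname(mc$vip), rep(1, 4), tolerance = 1e-3)

  # mean of squared VIPs is 1 on random data
  X <- matrix(rnorm(40 * 10), 40)
  m <- fit_oplsda(X, rep(c(0, 1), 20), n_ortho = 0)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-10)

  # one informative variable among noise at large n
  n <- 400
  yy <- rep(c(0, 1), each = n / 2)
  Xi <- cbind(info = yy + rnorm(n, 0, 0.5), matrix(rnorm(n * 15), n))
  mi <- fit_oplsda(Xi, yy, n_ortho = 0)
  expect_gt(mi$vip[1], 1)
  expect_lt(stats::median(mi$vip[-1]), 1)
})

test_that("training-score ROC is perfect on separable data", {
  set.seed(27)
  c1 <- c(rnorm(10, -3), rnorm(10, 3))
  X <- cbind(c1, c1 + rnorm(20, 0, 0.1))
  y <- rep(c("a", "b"), each = 10)
  m <- fit_oplsda(X, y, n_ortho = 0)
  expect_equal(roc_analysis(predict(m, X), y)$auc, 1)
  expect_equal(as.character(predict(m, X, type = "class")), as.character(y))
})

test_that("Q2Y: perfect prediction, null behavior, determinism", {
  set.seed(25)
  n <- 40
  y <- rep(c(-1, 1), each = n / 2)
  w <- c(1, -0.5, 2, 0.3)
  X <- outer(y, w) / sum(w^2) + matrix(rnorm(n * 4, 0, 1e-6), n)
  expect_gt(cross_validate(X, factor(y), n_ortho = 0), 0.99)

  # permuted labels: nonpositive Q2Y in expectation
  qs <- vapply(1:60, function(i) {
    Xr <- matrix(rnorm(24 * 6), 24)
    yr <- sample(rep(c(0, 1), 12))
    cross_validate(Xr, factor(yr), n_ortho = 0, seed = i)
  }, 0)
  expect_lt(mean(qs), 0)

  # same seed, same folds, same Q2Y
  Xd <- matrix(rnorm(30 * 5), 30); yd <- rep(c(0, 1), 15)
  expect_identical(cross_validate(Xd, yd, seed = 7),
                   cross_validate(Xd, yd, seed = 7))
})

test_that("permutation test: identity permutation and report structure", {
  set.seed(26)
  ch <- make_cohort(preset = "study-like", seed = 5)
  X <- as.matrix(ch$features[, -(1:2)])
  y <- ch$features$group

  # n_perm = 0: only the unpermuted fit
  v0 <- permutation_test(X, y, n_perm = 0, seed = 1)
  expect_null(v0$perm)
  expect_s3_class(v0$score_roc, "roc_result")

  # refitting on the identity permutation reproduces R2Y exactly
  m <- fit_oplsda(X, y, n_ortho = 0)
  v <- permutation_test(X, y, n_perm = 25, seed = 2)
  expect_equal(v$R2Y, m$R2Y, tolerance = 1e-12)
  expect_equal(nrow(v$perm), 25L)
  expect_true(all(is.finite(v$intercepts)))

  # informative cohort: permuted Q2Y below the unpermuted value
  expect_true(all(v$perm$Q2Y < v$Q2Y))
})

test_that("constant columns are dropped with a warning", {
  X <- cbind(rnorm(20), rep(1, 20), rnorm(20))
  expect_warning(m <- fit_oplsda(X, rep(c(0, 1), 10), n_ortho = 0), "constant")
  expect_equal(length(m$w), 2L)
})
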