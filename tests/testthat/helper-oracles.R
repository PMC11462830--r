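# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Exhaustive pairwise AUC with half credit for ties.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Pearson chi-square from first principles.
brute_chisq <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  expd <- outer(rs, cs) / n
  stat <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# NIPALS PLS1 (single component) on autoscaled X, centered y.
nipals_pls1 <- function(X, y) {
  Xc <- scale(X)
  yc <- y - mean(y)
  w <- as.vector(crossprod(Xc, yc))
  w <- w / sqrt(sum(w^2))
  t_sc <- as.vector(Xc %*% w)
  list(w = w, scores = t_sc, c = sum(yc * t_sc) / sum(t_sc^2))
}

# Numerical projection of a spherical function onto real SH via dense
# quadrature (independent of the least-squares SH fits in the package).
quad_sh_project <- function(fn, lmax, quad = sphere_quadrature(64L, 128L)) {
  Y <- sh_basis(quad$points, lmax)
  as.vector(crossprod(Y, fn(quad$points) * quad$weights))
}

# Rotational invariants from exact SH projection of a signal function.
quad_invariants <- function(fn, lmax = 4L, quad = sphere_quadrature(32L, 64L)) {
  cf <- quad_sh_project(fn, lmax, quad)
  ldeg <- sh_degrees_test(lmax)
  vapply(seq(0, lmax, 2), function(l) {
    sqrt(sum(cf[ldeg == l]^2)) / sqrt(4 * pi * (2 * l + 1))
  }, 0)
}

sh_degrees_test <- function(lmax) {
  unlist(lapply(seq(0, lmax, 2), function(l) rep(l, 2 * l + 1)))
}

# Voxel count of a rasterized circle: centers within radius r (mm).
brute_circle_count <- function(radius_mm, spacing) {
  r <- ceiling(radius_mm / spacing) + 1
  n <- 0
  for (i in -r:r) for (j in -r:r) {
    if ((i * spacing)^2 + (j * spacing)^2 <= radius_mm^2) n <- n + 1
  }
  n
}

# Random rotation matrix (deterministic under the caller's seed).
random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

# Shared protocol instance; cheap to rebuild but convenient.
test_scheme <- function() study_scheme()

# Small shared SMI estimator: trained once per session at reduced size to
# keep the suite fast; accuracy documented in the vignette.
smi_test_estimator <- local({
  est <- NULL
  function() {
    if (is.null(est)) est <<- train_smi_estimator(n_train = 200000L)
    est
  }
})
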