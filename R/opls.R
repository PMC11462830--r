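#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary outcome: y-orthogonal variation is removed from the (autoscaled)
#' predictor matrix component by component, then a single predictive PLS
#' component is fit to the filtered matrix. With `n_ortho = 0` the model is
#' exactly PLS1. The fit is deterministic.
#'
#' @param X numeric matrix (patients x variables), no missing values
#' @param y binary labels (factor, character or +/-1); dummy-coded internally
#' @param n_ortho number of orthogonal components; `"auto"` selects by
#'   forward addition while cross-validated Q2Y improves by >= `delta_q2`
#'   (cap `max_ortho`)
#' @param scaling "uv" (unit variance, default) or "center"
#' @param delta_q2,max_ortho auto-selection controls
#' @param folds,cv_seed cross-validation controls used when `n_ortho="auto"`
#' @return object of class `oplsda`: predictive weights `w` (unit norm),
#'   loadings `p`, scores `t`, y-loading `c`, orthogonal `W_o`, `P_o`, `T_o`,
#'   scaling parameters, `R2Y`, `vip`
#' @export
fit_oplsda <- function(X, y, n_ortho = 0, scaling = c("uv", "center"),
                       delta_q2 = 0.01, max_ortho = 3L, folds = 7L,
                       cv_seed = 1L) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete")
  if (nrow(X) < 6) stop("need n >= 6")
  yv <- encode_y(y)
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant column(s)", sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  if (identical(n_ortho, "auto")) {
    q_prev <- cross_validate(X, y, folds = folds, n_ortho = 0, seed = cv_seed)
    n_sel <- 0L
    while (n_sel < max_ortho && n_sel < qr(scale(X))$rank - 1) {
      q_next <- cross_validate(X, y, folds = folds, n_ortho = n_sel + 1L, seed = cv_seed)
      if (q_next - q_prev < delta_q2) break
      q_prev <- q_next
      n_sel <- n_sel + 1L
    }
    n_ortho <- n_sel
  }
  fit <- opls_core(X, yv, n_ortho, scaling)
  fit$kept_columns <- keep
  fit$y_levels <- attr(yv, "levels")
  fit$vip <- vip_from_fit(fit)
  class(fit) <- "oplsda"
  fit
}

encode_y <- function(y) {
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    structure(as.numeric(y), levels = c("-1", "1"))
  } else {
    f <- as.factor(y)
    if (nlevels(f) != 2) stop("y must be binary")
    structure(ifelse(as.integer(f) == 1, -1, 1), levels = levels(f))
  }
}

opls_core <- function(X, yv, n_ortho, scaling) {
  mx <- colMeans(X)
  sx <- if (scaling == "uv") apply(X, 2, stats::sd) else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, mx), 2, sx, `/`)
  my <- mean(yv)
  yc <- yv - my
  if (n_ortho >= min(dim(Xc))) stop("n_ortho must be below the rank of X")

  w <- as.vector(crossprod(Xc, yc))
  w <- w / sqrt(sum(w^2))
  W_o <- P_o <- NULL
  T_o <- NULL
  Xf <- Xc
  for (k in seq_len(n_ortho)) {
    t_p <- as.vector(Xf %*% w)
    p <- as.vector(crossprod(Xf, t_p)) / sum(t_p^2)
    w_o <- p - sum(w * p) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw
    t_o <- as.vector(Xf %*% w_o)
    p_o <- as.vector(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  t_p <- as.vector(Xf %*% w)
  p <- as.vector(crossprod(Xf, t_p)) / sum(t_p^2)
  cc <- sum(yc * t_p) / sum(t_p^2)
  yhat <- t_p * cc
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  list(w = w, p = p, c = cc, t = t_p, W_o = W_o, P_o = P_o, T_o = T_o,
       n_ortho = if (is.null(T_o)) 0L else ncol(T_o),
       x_center = mx, x_scale = sx, y_center = my, R2Y = r2y)
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal component(s), R2Y = %.3f\n",
              x$n_ortho, x$R2Y))
  v <- sort(x$vip, decreasing = TRUE)
  cat("Top VIP:", paste(sprintf("%s (%.2f)", names(v)[seq_len(min(5, length(v)))],
                                v[seq_len(min(5, length(v)))]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.oplsda <- function(object, ...) {
  stats::setNames(object$w * object$c / object$x_scale,
                  names(object$x_center))
}

#' @export
predict.oplsda <- function(object, newdata, type = c("score", "response", "class"), ...) {
  type <- match.arg(type)
  Xn <- as.matrix(newdata)
  if (!is.null(object$kept_columns) && ncol(Xn) == length(object$kept_columns)) {
    Xn <- Xn[, object$kept_columns, drop = FALSE]
  }
  Xc <- sweep(sweep(Xn, 2, object$x_center), 2, object$x_scale, `/`)
  if (object$n_ortho > 0) {
    for (k in seq_len(object$n_ortho)) {
      t_o <- as.vector(Xc %*% object$W_o[, k])
      Xc <- Xc - tcrossprod(t_o, object$P_o[, k])
    }
  }
  t_p <- as.vector(Xc %*% object$w)
  if (type == "score") return(t_p)
  yh <- t_p * object$c + object$y_center
  if (type == "response") return(yh)
  factor(object$y_levels[ifelse(yh >= 0, 2, 1)], levels = object$y_levels)
}

#' @export
summary.oplsda <- function(object, ...) {
  cat(sprintf("OPLS-DA model: %d variables, %d orthogonal component(s)\n",
              length(object$w), object$n_ortho))
  cat(sprintf("R2Y = %.4f\n", object$R2Y))
  cat("VIP (descending):\n")
  print(round(sort(object$vip, decreasing = TRUE), 3))
  invisible(object)
}

vip_from_fit <- function(fit) {
  p_vars <- length(fit$w)
  v <- sqrt(p_vars * fit$w^2)   # single predictive component: VIP_j = sqrt(p) |w_j|
  names(v) <- names(fit$x_center)
  v
}

#' Variable importance in projection
#'
#' Predictive-component VIP: \eqn{VIP_j = \sqrt{p}\,|w_j|} for the unit-norm
#' predictive weight vector, so that the mean of squared VIP values is 1 and
#' values above 1 mark variables contributing more than average.
#'
#' @param model a fitted `oplsda`
#' @return named numeric vector
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  model$vip
}

#' Cross-validated predictive ability Q2Y
#'
#' Stratified k-fold cross-validation of the OPLS-DA model:
#' \eqn{Q^2Y = 1 - PRESS / SS_Y} with out-of-fold predictions of the
#' dummy-coded outcome. Fold assignment is seed-reproducible and stratified
#' by class; a configuration leaving a fold without both classes is
#' re-stratified by construction.
#'
#' @param X predictor matrix
#' @param y binary labels
#' @param folds number of folds (default 7)
#' @param n_ortho orthogonal components
#' @param seed fold-assignment seed
#' @param scaling passed to the inner fits
#' @return Q2Y (scalar)
#' @export
cross_validate <- function(X, y, folds = 7L, n_ortho = 0L, seed = 1L,
                           scaling = "uv") {
  X <- as.matrix(X)
  yv <- encode_y(y)
  n <- length(yv)
  stopifnot(folds >= 2)
  fold_id <- with_seed(seed, {
    id <- integer(n)
    for (cls in unique(yv)) {
      idx <- sample(which(yv == cls))
      id[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    id
  })
  press <- 0
  for (k in seq_len(folds)) {
    test <- fold_id == k
    if (all(test) || !any(test)) next
    keep <- apply(X[!test, , drop = FALSE], 2, stats::sd) > 0
    fit <- opls_core(X[!test, keep, drop = FALSE], yv[!test], n_ortho, scaling)
    Xc <- sweep(sweep(X[test, keep, drop = FALSE], 2, fit$x_center), 2, fit$x_scale, `/`)
    if (fit$n_ortho > 0) {
      for (j in seq_len(fit$n_ortho)) {
        t_o <- as.vector(Xc %*% fit$W_o[, j])
        Xc <- Xc - tcrossprod(t_o, fit$P_o[, j])
      }
    }
    yh <- as.vector(Xc %*% fit$w) * fit$c + fit$y_center
    press <- press + sum((yv[test] - yh)^2)
  }
  1 - press / sum((yv - mean(yv))^2)
}

#' Out-of-fold OPLS-DA scores
#'
#' Same stratified fold machinery as [cross_validate()], returning each
#' patient's predictive score from the model fit without that patient's fold;
#' the ROC of these scores is the cross-validated estimate of the
#' multiparametric model's discrimination.
#'
#' @inheritParams cross_validate
#' @return numeric vector of out-of-fold scores (same order as rows of X)
#' @export
cv_scores <- function(X, y, folds = 7L, n_ortho = 0L, seed = 1L, scaling = "uv") {
  X <- as.matrix(X)
  yv <- encode_y(y)
  n <- length(yv)
  fold_id <- with_seed(seed, {
    id <- integer(n)
    for (cls in unique(yv)) {
      idx <- sample(which(yv == cls))
      id[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    id
  })
  out <- numeric(n)
  for (k in seq_len(folds)) {
    test <- fold_id == k
    if (!any(test)) next
    keep <- apply(X[!test, , drop = FALSE], 2, stats::sd) > 0
    fit <- opls_core(X[!test, keep, drop = FALSE], yv[!test], n_ortho, scaling)
    Xc <- sweep(sweep(X[test, keep, drop = FALSE], 2, fit$x_center), 2, fit$x_scale, `/`)
    if (fit$n_ortho > 0) {
      for (j in seq_len(fit$n_ortho)) {
        t_o <- as.vector(Xc %*% fit$W_o[, j])
        Xc <- Xc - tcrossprod(t_o, fit$P_o[, j])
      }
    }
    out[test] <- as.vector(Xc %*% fit$w) * fit$c + fit$y_center
  }
  out
}

#' Permutation test of OPLS-DA model validity
#'
#' Refits the model on `n_perm` label permutations, recording R2Y, Q2Y and
#' the absolute correlation of each permuted label vector with the original;
#' reports the ordinary-least-squares intercepts of R2Y and Q2Y regressed on
#' that correlation (including the unpermuted point, the usual
#' validation-plot convention), together with the unpermuted model, its Q2Y
#' and the ROC of
#' its scores. Intercepts near or below chance level (R2Y intercept < 0.3,
#' Q2Y intercept < 0.05 conventionally) indicate the unpermuted fit is not
#' an overfitting artifact.
#'
#' @param X predictor matrix
#' @param y binary labels
#' @param n_perm number of permutations (0 = only the unpermuted fit)
#' @param seed permutation seed
#' @param n_ortho orthogonal components (fixed across permutations)
#' @param folds CV folds for Q2Y
#' @return object of class `opls_validation`: `model`, `R2Y`, `Q2Y`,
#'   `score_roc`, `perm` (data frame cor/R2Y/Q2Y), `intercepts`
#' @export
permutation_test <- function(X, y, n_perm = 200L, seed = 1L, n_ortho = 0L,
                             folds = 7L) {
  X <- as.matrix(X)
  yv <- encode_y(y)
  model <- fit_oplsda(X, y, n_ortho = n_ortho)
  r2y0 <- model$R2Y
  q2y0 <- cross_validate(X, y, folds = folds, n_ortho = n_ortho, seed = seed)
  roc0 <- roc_analysis(predict(model, X), y)
  perm <- NULL
  if (n_perm > 0) {
    perm <- with_seed(derive_seed(seed, "permutation"), {
      do.call(rbind, lapply(seq_len(n_perm), function(i) {
        yp <- sample(yv)
        fp <- opls_core(X, yp, n_ortho, "uv")
        qp <- cross_validate(X, yp, folds = folds, n_ortho = n_ortho,
                             seed = seed + i)
        data.frame(cor = abs(stats::cor(yp, yv)), R2Y = fp$R2Y, Q2Y = qp)
      }))
    })
  }
  pts <- rbind(data.frame(cor = 1, R2Y = r2y0, Q2Y = q2y0), perm)
  ints <- c(R2Y = unname(stats::coef(stats::lm(R2Y ~ cor, pts))[1]),
            Q2Y = unname(stats::coef(stats::lm(Q2Y ~ cor, pts))[1]))
  structure(list(model = model, R2Y = r2y0, Q2Y = q2y0, score_roc = roc0,
                 perm = perm, intercepts = ints, n_perm = n_perm),
            class = "opls_validation")
}

#' @export
print.opls_validation <- function(x, ...) {
  cat(sprintf("OPLS-DA validation: R2Y %.3f, Q2Y %.3f, score AUC %.3f\n",
              x$R2Y, x$Q2Y, x$score_roc$auc))
  if (!is.null(x$perm)) {
    cat(sprintf("  %d permutations: max permuted Q2Y %.3f; intercepts R2Y %.3f, Q2Y %.3f\n",
                nrow(x$perm), max(x$perm$Q2Y), x$intercepts["R2Y"], x$intercepts["Q2Y"]))
  }
  invisible(x)
}
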