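#' Aggregate parameter maps over ROIs into one patient's feature row
#'
#' Each metric value is the unweighted mean of the per-ROI means over the
#' tumor ROIs (ROIs weighted equally, not pooled voxels); with
#' `normalize = TRUE` a second set of values divided by the contralateral
#' reference-ROI mean is appended with suffix `_norm`.
#'
#' @param maps named list of 3D arrays (one per metric) on a common grid
#' @param rois a `roi_set`
#' @param normalize also emit contralateral-normalized values
#' @return named list (one row of a cohort feature table)
#' @export
aggregate_roi <- function(maps, rois, normalize = FALSE) {
  stopifnot(inherits(rois, "roi_set"))
  for (m in rois$tumor_rois) {
    if (!any(m)) stop("empty tumor ROI")
    if (!all(dim(m) == dim(maps[[1]]))) stop("ROI and map grids differ")
  }
  row <- lapply(maps, function(vol) {
    mean(vapply(rois$tumor_rois, function(m) mean(vol[m]), 0))
  })
  if (normalize) {
    if (is.null(rois$reference_roi)) stop("normalization requires a reference ROI")
    for (nm in names(maps)) {
      ref <- mean(maps[[nm]][rois$reference_roi])
      row[[paste0(nm, "_norm")]] <- row[[nm]] / ref
    }
  }
  row
}

#' Two-group comparison with normality-dependent test routing
#'
#' Shapiro-Wilk on each group at alpha = 0.05 decides the route: if both
#' groups look normal, a two-sample t-test is used (pooled variance when
#' Levene's test accepts homogeneity, Welch otherwise); otherwise the
#' Mann-Whitney U test with normal approximation and tie correction.
#'
#' @param feature numeric vector
#' @param labels two-level factor/character vector
#' @param alpha normality-screening level
#' @return object of class `group_test`: test, statistic, p, group summaries
#' @export
compare_groups <- function(feature, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2)
  gs <- split(feature, labels)
  if (any(vapply(gs, length, 0L) < 3)) stop("each group needs n >= 3")
  summ <- lapply(gs, function(v) c(mean = mean(v), sd = stats::sd(v), median = stats::median(v)))
  if (all(vapply(gs, stats::sd, 0) == 0)) {
    return(structure(list(test = "degenerate (constant feature)", statistic = NA_real_,
                          p = 1, groups = summ, flags = "constant feature"),
                     class = "group_test"))
  }
  normal <- all(vapply(gs, function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha
  }, TRUE))
  if (normal) {
    lev <- car::leveneTest(feature ~ labels)
    equal_var <- lev[1, "Pr(>F)"] >= alpha
    tt <- stats::t.test(feature ~ labels, var.equal = equal_var)
    res <- list(test = if (equal_var) "t-test (pooled)" else "t-test (Welch)",
                statistic = unname(tt$statistic), p = tt$p.value,
                groups = summ, flags = character(0))
  } else {
    wt <- stats::wilcox.test(feature ~ labels, exact = FALSE, correct = TRUE)
    res <- list(test = "Mann-Whitney U", statistic = unname(wt$statistic),
                p = wt$p.value, groups = summ, flags = character(0))
  }
  structure(res, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g\n", x$test, x$statistic, x$p))
  invisible(x)
}

#' Pearson chi-square test for R x C count tables
#'
#' Pearson chi-square without continuity correction,
#' df = (R-1)(C-1), with expected counts reported. This is the convention
#' that reproduces published clinical-characteristics tables for 2 x 2 data.
#'
#' @param table nonnegative integer matrix
#' @return object of class `group_test` with `expected` attached
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) stop("zero marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(test = "Pearson chi-square", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 expected = ct$expected, flags = character(0)),
            class = "group_test")
}

#' ROC analysis of a single feature
#'
#' AUC via the Mann-Whitney identity with DeLong 95% confidence interval;
#' orientation is auto-flipped so AUC >= 0.5 (flag recorded); the operating
#' point maximizes Youden's J (ties broken by the lowest threshold).
#'
#' @param feature numeric scores
#' @param labels two-level labels; the second factor level is "positive"
#' @return object of class `roc_result`: auc, ci, sensitivity, specificity,
#'   threshold, flipped
#' @export
roc_analysis <- function(feature, labels) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2)
  if (any(table(labels) == 0)) stop("both classes must be present")
  r <- pROC::roc(labels, feature, quiet = TRUE, direction = "<",
                 levels = levels(labels))
  flipped <- FALSE
  if (as.numeric(pROC::auc(r)) < 0.5) {
    r <- pROC::roc(labels, feature, quiet = TRUE, direction = ">",
                   levels = levels(labels))
    flipped <- TRUE
  }
  auc <- as.numeric(pROC::auc(r))
  ci <- if (stats::sd(feature) == 0) c(0.5, 0.5) else {
    as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))[c(1, 3)]
  }
  # degenerate variance (e.g. heavy ties) collapses the CI onto the estimate
  if (any(!is.finite(ci))) ci <- c(auc, auc)
  ci <- clamp(ci, 0, 1)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  j <- co$sensitivity + co$specificity - 1
  best <- which(j == max(j))
  best <- best[which.min(co$threshold[best])]
  structure(list(auc = auc, ci = ci, sensitivity = co$sensitivity[best],
                 specificity = co$specificity[best],
                 threshold = co$threshold[best], flipped = flipped),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), sens %.3f, spec %.3f%s\n",
              x$auc, x$ci[1], x$ci[2], x$sensitivity, x$specificity,
              if (x$flipped) " [orientation flipped]" else ""))
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' Z test for the difference of correlated (same-patient) AUCs.
#'
#' @param feature_a,feature_b scores for the same patients
#' @param labels two-level labels
#' @return `group_test` with the Z statistic and two-sided p
#' @export
delong_compare <- function(feature_a, feature_b, labels) {
  labels <- as.factor(labels)
  ra <- pROC::roc(labels, feature_a, quiet = TRUE, direction = "auto", levels = levels(labels))
  rb <- pROC::roc(labels, feature_b, quiet = TRUE, direction = "auto", levels = levels(labels))
  if (isTRUE(all.equal(feature_a, feature_b))) {
    return(structure(list(test = "DeLong Z (paired)", statistic = 0, p = 1,
                          flags = "identical features"), class = "group_test"))
  }
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  structure(list(test = "DeLong Z (paired)", statistic = unname(tt$statistic),
                 p = tt$p.value, flags = character(0)),
            class = "group_test")
}

#' Apply patient exclusion criteria in order
#'
#' Removes candidates failing any criterion and reports per-criterion removal
#' counts in application order (a candidate is counted at the first criterion
#' that removes it).
#'
#' @param candidates data frame with one row per candidate
#' @param criteria named list of logical vectors (TRUE = excluded)
#' @return list `included` (data frame), `removed` (named counts),
#'   `n_included`
#' @export
exclusion_filter <- function(candidates, criteria) {
  keep <- rep(TRUE, nrow(candidates))
  removed <- integer(length(criteria))
  names(removed) <- names(criteria)
  for (i in seq_along(criteria)) {
    hit <- keep & criteria[[i]]
    removed[i] <- sum(hit)
    keep <- keep & !criteria[[i]]
  }
  list(included = candidates[keep, , drop = FALSE], removed = removed,
       n_included = sum(keep))
}

#' Published clinical-characteristics count tables
#'
#' The 2 x 2 (and R x C) group-by-level count tables of the study cohort's
#' clinical characteristics (rows = levels, columns = non-recurrence /
#' recurrence), together with the patient-flow counts, shipped as package
#' data so the univariate statistics can be recomputed from printed inputs.
#'
#' @return list of integer matrices plus `flow` (candidate and exclusion
#'   counts)
#' @export
clinical_reference_counts <- function() {
  path <- system.file("extdata", "clinical_table_counts.csv", package = "gliomicro")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tabs <- lapply(split(df, df$variable), function(d) {
    m <- as.matrix(d[, c("non_recurrence", "recurrence")])
    rownames(m) <- d$level
    m
  })
  tabs$flow <- c(candidates = 169L, no_routine_mri = 42L,
                 incomplete_resection = 3L, no_postop_mri = 76L)
  tabs
}

#' Univariate statistics table for a cohort feature table
#'
#' Runs [compare_groups()] for every metric column, mirroring the published
#' analysis (no multiple-testing correction), with a Benjamini-Hochberg
#' column emitted alongside for transparency.
#'
#' @param features cohort feature data frame (patient, group, metrics...)
#' @return data frame: metric, test, p, p_BH, group means/SDs
#' @export
cohort_group_stats <- function(features) {
  metrics <- setdiff(names(features), c("patient", "group"))
  rows <- lapply(metrics, function(m) {
    gt <- compare_groups(features[[m]], features$group)
    data.frame(metric = m, test = gt$test, p = gt$p,
               mean_nonrec = gt$groups[[1]]["mean"], sd_nonrec = gt$groups[[1]]["sd"],
               mean_rec = gt$groups[[2]]["mean"], sd_rec = gt$groups[[2]]["sd"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_BH <- stats::p.adjust(out$p, method = "BH")
  out
}

#' ROC table for a cohort feature table
#'
#' [roc_analysis()] per metric: AUC, DeLong 95% CI, Youden-optimal
#' sensitivity/specificity.
#'
#' @param features cohort feature data frame
#' @return data frame, one row per metric
#' @export
cohort_roc_table <- function(features) {
  metrics <- setdiff(names(features), c("patient", "group"))
  rows <- lapply(metrics, function(m) {
    r <- roc_analysis(features[[m]], features$group)
    data.frame(metric = m, auc = r$auc, ci_lo = r$ci[1], ci_hi = r$ci[2],
               sensitivity = r$sensitivity, specificity = r$specificity,
               flipped = r$flipped)
  })
  do.call(rbind, rows)
}
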