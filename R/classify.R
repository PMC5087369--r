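# Fisher linear discriminant combination of AQR/VLP features and the
# clinical performance indices: specificity (on normals), sensitivity (on VT
# patients), total prediction accuracy and ROC area. VT is the positive
# class throughout.

# Coerce a feature table (data frame with subject_id/label + numeric columns,
# or a bare matrix) into a feature matrix plus a normal/vt factor.
feature_matrix <- function(table, labels = NULL) {
  if (is.data.frame(table)) {
    if (is.null(labels)) labels <- table$label
    drop <- intersect(c("subject_id", "label"), names(table))
    x <- as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
  } else {
    x <- as.matrix(table)
  }
  storage.mode(x) <- "double"
  labels <- factor(labels, levels = c("normal", "vt"))
  if (anyNA(labels) || nrow(x) != length(labels))
    stop_aiqp("invalid_input", "labels must be 'normal'/'vt', one per row")
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message(sprintf("dropping %d subject(s) with missing features", sum(!keep)))
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (!all(is.finite(x)))
    stop_aiqp("invalid_input", "features must be finite")
  list(x = x, labels = labels)
}

#' Fisher linear discriminant analysis
#'
#' Two-class Fisher LDA: the discriminant direction is
#' `pooled-within-class-covariance^-1 %*% (mean_vt - mean_normal)`, with the
#' pooled covariance pseudo-inverted (relative tolerance 1e-10) so that
#' collinear feature sets — e.g. 60 correlated AQR parameters on 72 subjects
#' — still yield a discriminant. The orientation is fixed so the VT class has
#' the higher mean score. A warning names the collinear columns when the
#' pooled covariance is rank deficient.
#'
#' @param table data frame with a `label` column (`"normal"`/`"vt"`) and
#'   numeric feature columns (a `subject_id` column is ignored), or a numeric
#'   matrix with `labels` supplied separately.
#' @param labels optional label vector when `table` is a matrix.
#' @return Object of class `fisher_lda`: list with `weights` (named vector),
#'   `scores` (per subject), `labels`, `means` (class mean vectors) and
#'   `rank_deficient` flag.
#' @export
fisher_lda <- function(table, labels = NULL) {
  fm <- feature_matrix(table, labels)
  x <- fm$x; lab <- fm$labels
  if (min(table(lab)) < 2)
    stop_aiqp("invalid_input", "need at least 2 subjects per class")
  xn <- x[lab == "normal", , drop = FALSE]
  xv <- x[lab == "vt", , drop = FALSE]
  mu_n <- colMeans(xn); mu_v <- colMeans(xv)
  sw <- ((nrow(xn) - 1) * stats::cov(xn) + (nrow(xv) - 1) * stats::cov(xv)) /
    (nrow(x) - 2)
  qr_sw <- qr(sw, tol = 1e-10)
  rank_deficient <- qr_sw$rank < ncol(x)
  if (rank_deficient) {
    collinear <- colnames(x)[qr_sw$pivot[-seq_len(qr_sw$rank)]]
    warning(sprintf(
      "pooled covariance is rank deficient (%d < %d); pseudo-inverse used. Collinear columns include: %s",
      qr_sw$rank, ncol(x), paste(utils::head(collinear, 8), collapse = ", ")),
      call. = FALSE)
  }
  w <- as.vector(MASS::ginv(sw, tol = 1e-10) %*% (mu_v - mu_n))
  scores <- as.vector(x %*% w)
  if (mean(scores[lab == "vt"]) < mean(scores[lab == "normal"])) {
    w <- -w; scores <- -scores
  }
  names(w) <- colnames(x)
  structure(list(weights = w, scores = scores, labels = lab,
                 means = rbind(normal = mu_n, vt = mu_v),
                 rank_deficient = rank_deficient),
            class = "fisher_lda")
}

#' Classification performance at a fixed threshold
#'
#' Predicts VT when the discriminant score is `>= threshold` and reports the
#' confusion counts with specificity `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`
#' and total prediction accuracy `(TP+TN)/n`, all in percent.
#'
#' @param scores per-subject discriminant scores.
#' @param labels `"normal"`/`"vt"` labels, aligned with `scores`.
#' @param threshold score cutoff.
#' @return Object of class `performance_report`: list with `sp`, `se`, `tpa`
#'   (percent), `threshold`, `confusion` (named TP/FN/TN/FP counts) and `auc`
#'   (`NA` here; filled by [lda_performance()]).
#' @examples
#' classify_metrics(c(1, 2, 8, 9), c("normal", "normal", "vt", "vt"), 5)
#' @export
classify_metrics <- function(scores, labels, threshold) {
  labels <- factor(labels, levels = c("normal", "vt"))
  if (length(scores) != length(labels) || anyNA(labels))
    stop_aiqp("invalid_input", "scores and normal/vt labels must align")
  if (nlevels(droplevels(labels)) < 2)
    stop_aiqp("invalid_input", "both classes must be present")
  pred_vt <- scores >= threshold
  tp <- sum(pred_vt & labels == "vt")
  fn <- sum(!pred_vt & labels == "vt")
  tn <- sum(!pred_vt & labels == "normal")
  fp <- sum(pred_vt & labels == "normal")
  structure(list(
    sp = 100 * tn / (tn + fp),
    se = 100 * tp / (tp + fn),
    tpa = 100 * (tp + tn) / length(scores),
    threshold = threshold,
    confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
    auc = NA_real_),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> SP %.1f%%, SE %.1f%%, TPA %.1f%%%s (threshold %.4g)\n",
              x$sp, x$se, x$tpa,
              if (is.na(x$auc)) "" else sprintf(", AUC %.1f%%", x$auc),
              x$threshold))
  cat(sprintf("  confusion: TP %d, FN %d, TN %d, FP %d\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  invisible(x)
}

#' Area under the ROC curve
#'
#' AUC computed as the normalized Mann-Whitney statistic: the fraction of
#' (VT, normal) score pairs ranked correctly, ties credited 1/2. This equals
#' the trapezoidal area under the empirical ROC curve. Reported in percent.
#'
#' @inheritParams classify_metrics
#' @return scalar AUC in percent (50 = chance, 100 = perfect separation).
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(labels, levels = c("normal", "vt"))
  if (length(scores) != length(labels) || anyNA(labels))
    stop_aiqp("invalid_input", "scores and normal/vt labels must align")
  n_vt <- sum(labels == "vt"); n_no <- sum(labels == "normal")
  if (n_vt == 0 || n_no == 0)
    stop_aiqp("invalid_input", "both classes must be present")
  r <- rank(scores)
  u <- sum(r[labels == "vt"]) - n_vt * (n_vt + 1) / 2
  100 * u / (n_vt * n_no)
}

#' Empirical ROC curve points
#'
#' Sensitivity/1-specificity pairs over all distinct thresholds, for plotting
#' or export.
#'
#' @inheritParams classify_metrics
#' @return data frame with columns `threshold`, `fpr`, `tpr` (fractions).
#' @export
roc_points <- function(scores, labels) {
  labels <- factor(labels, levels = c("normal", "vt"))
  thr <- c(sort(unique(scores)), Inf)
  do.call(rbind, lapply(thr, function(t) {
    data.frame(threshold = t,
               fpr = mean(scores[labels == "normal"] >= t),
               tpr = mean(scores[labels == "vt"] >= t))
  }))
}

#' Threshold maximizing total prediction accuracy
#'
#' Scans the midpoints between adjacent sorted unique scores (plus sentinels
#' below and above the score range) and returns the cutoff with maximal TPA.
#' Ties break toward higher specificity, then toward the smaller threshold,
#' so the result is deterministic.
#'
#' @inheritParams classify_metrics
#' @return scalar threshold.
#' @export
best_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             u[length(u)] + 1)
  best <- NULL
  for (t in cands) {
    m <- classify_metrics(scores, labels, t)
    if (is.null(best) || m$tpa > best$tpa + 1e-12 ||
        (abs(m$tpa - best$tpa) <= 1e-12 && m$sp > best$sp + 1e-12))
      best <- list(tpa = m$tpa, sp = m$sp, threshold = t)
  }
  best$threshold
}

#' Discriminant performance of a feature table
#'
#' Convenience wrapper running [fisher_lda()], [best_threshold()],
#' [classify_metrics()] and [roc_auc()] on one feature table: the apparent
#' (training-set) performance of the feature combination, matching how
#' multi-parameter AQR combinations are evaluated.
#'
#' @inheritParams fisher_lda
#' @return a `performance_report` with `auc` filled in and the fitted
#'   `fisher_lda` object attached as attribute `lda`.
#' @export
lda_performance <- function(table, labels = NULL) {
  fit <- fisher_lda(table, labels)
  thr <- best_threshold(fit$scores, fit$labels)
  rep <- classify_metrics(fit$scores, fit$labels, thr)
  rep$auc <- roc_auc(fit$scores, fit$labels)
  attr(rep, "lda") <- fit
  rep
}
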