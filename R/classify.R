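#' Train an RBF-kernel support vector machine
#'
#' Soft-margin SVM with Gaussian radial basis kernel (libsvm via e1071).
#' Defaults `C = 0.8`, `gamma = 1`; feature scaling is the caller's
#' responsibility (see [loocv_scores()], which standardizes inside each
#' fold).
#'
#' @param X Numeric matrix, patients x features (already standardized).
#' @param y Binary labels (0/1); both classes must be present.
#' @param C Soft-margin penalty (default 0.8).
#' @param gamma RBF kernel width (default 1).
#' @param ... Further arguments for [e1071::svm()] (e.g. `tolerance`).
#' @return Object of class `rfrad_svm`; use [decision_values()] to score
#'   new data (positive scores favour class 1).
#' @export
train_svm <- function(X, y, C = 0.8, gamma = 1, ...) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("need at least one feature", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present in training data", call. = FALSE)
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE, ...)
  structure(list(fit = fit), class = "rfrad_svm")
}

#' Signed decision values of an SVM
#'
#' @param model An [train_svm()] fit.
#' @param X New data matrix (same columns as training).
#' @return Numeric scores; `score > 0` predicts class 1.
#' @export
decision_values <- function(model, X) {
  pr <- stats::predict(model$fit, as.matrix(X), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm names the column "A/B": positive values vote for class A
  score <- as.numeric(dv[, 1])
  if (startsWith(colnames(dv)[1], "0")) score <- -score
  score
}

#' Leave-one-out cross-validated radiomics scores
#'
#' For each patient the remaining `n - 1` rows are rescaled feature-wise to
#' `[0, 1]` (the scaling the libsvm tooling recommends for RBF kernels; a
#' z-score would put standardized distances in the regime where
#' `exp(-gamma * d^2)` underflows at `gamma = 1` and every held-out score
#' collapses to the intercept), an SVM is trained on the top-`k` features
#' of `ranking`, and the held-out patient is scored with the
#' training-fold scaling. The feature ranking itself is computed once on
#' the full table, mirroring the single global ranking of the original
#' workflow; note this is a mild selection-level leak and is documented as
#' such.
#'
#' @param table Feature table (see [feature_columns()]).
#' @param ranking An [rank_by_src()] result (or character vector of feature
#'   names in rank order). Ignored when `refit_ranking = TRUE`.
#' @param k Number of top-ranked features to use.
#' @param C,gamma SVM parameters (defaults 0.8, 1).
#' @param refit_ranking Recompute the SRC ranking inside every fold
#'   (leak-free nested protocol). Default `FALSE`: one global ranking, as
#'   in the original workflow. See the selection-bias discussion in the
#'   methods vignette.
#' @return Tibble: `patient_id`, `label`, `score` (LOOCV decision value,
#'   the per-patient radiomics score), `pred` (0/1 at threshold 0).
#' @export
loocv_scores <- function(table, ranking = NULL, k, C = 0.8, gamma = 1,
                         refit_ranking = FALSE) {
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 patients for LOOCV", call. = FALSE)
  if (length(unique(table$label)) < 2L) stop("all patients share one label", call. = FALSE)
  if (is.null(ranking) && !refit_ranking) {
    stop("supply `ranking`, or set `refit_ranking = TRUE`", call. = FALSE)
  }
  y <- table$label
  if (!refit_ranking) {
    feats <- if (is.character(ranking)) ranking else ranking$feature
    feats <- feats[seq_len(min(k, length(feats)))]
  }
  score <- vapply(seq_len(n), function(i) {
    fold_feats <- if (refit_ranking) {
      rk <- rank_by_src(table[-i, ])
      rk$feature[seq_len(min(k, nrow(rk)))]
    } else feats
    X <- as.matrix(table[fold_feats])
    Xtr <- X[-i, , drop = FALSE]
    lo <- apply(Xtr, 2L, min)
    rg <- apply(Xtr, 2L, max) - lo
    rg[rg == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2L, lo), 2L, rg, `/`)
    xte <- (X[i, ] - lo) / rg
    m <- train_svm(Xs, y[-i], C = C, gamma = gamma)
    decision_values(m, matrix(xte, nrow = 1L))
  }, numeric(1))
  tibble::tibble(patient_id = table$patient_id, label = y,
                 score = score, pred = as.integer(score > 0))
}

#' Classification metrics at a fixed threshold
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy, with
#' label 1 as the positive class, reported in percent.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold on the scores (default 0).
#' @return Named numeric vector `c(acc, sens, spec)` in percent.
#' @export
binary_metrics <- function(scores, labels, threshold = 0) {
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  pred <- scores > threshold
  pos <- labels == 1
  c(acc = 100 * mean(pred == pos),
    sens = 100 * sum(pred & pos) / sum(pos),
    spec = 100 * sum(!pred & !pos) / sum(!pos))
}

#' Mann-Whitney AUC
#'
#' Probability that a random positive scores above a random negative, with
#' ties counting one half — the area under the empirical ROC curve.
#'
#' @inheritParams binary_metrics
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve, AUC and bootstrap confidence interval
#'
#' ROC points over all score thresholds; AUC by the Mann-Whitney statistic;
#' 95% CI by stratified bootstrap (resampling within classes, 2000
#' replicates by default). Seed the session RNG for reproducible CIs.
#'
#' @inheritParams binary_metrics
#' @param n_boot Bootstrap replicates for the CI (default 2000).
#' @param conf Confidence level (default 0.95).
#' @return List: `points` (tibble `fpr`, `tpr`, from (0,0) to (1,1)),
#'   `auc`, `ci` (length-2 vector).
#' @export
roc_auc <- function(scores, labels, n_boot = 2000L, conf = 0.95) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- tibble::tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  auc <- auc_mw(scores, labels)
  ipos <- which(labels == 1); ineg <- which(labels == 0)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
    auc_mw(scores[idx], labels[idx])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(points = pts, auc = auc,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))))
}

#' Precision-recall curve and break-even point
#'
#' Precision and recall over all decision thresholds (predict positive at
#' `score >= t`). The break-even point (BEP) is the precision where
#' precision equals recall, linearly interpolated between the adjacent
#' thresholds when the curves cross between them.
#'
#' @inheritParams binary_metrics
#' @return List: `points` (tibble `threshold`, `recall`, `precision`),
#'   `bep`.
#' @export
prc_bep <- function(scores, labels) {
  if (sum(labels == 1) < 1L) stop("need at least one positive", call. = FALSE)
  th <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == 1
  pts <- purrr::map_dfr(th, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   recall = sum(pred & pos) / sum(pos),
                   precision = sum(pred & pos) / max(sum(pred), 1L))
  })
  d <- pts$precision - pts$recall
  cross <- which(d[-length(d)] * d[-1] <= 0)
  if (length(cross) > 0L) {
    i <- cross[1]
    w <- if (d[i] == d[i + 1]) 0 else d[i] / (d[i] - d[i + 1])
    bep <- pts$precision[i] + w * (pts$precision[i + 1] - pts$precision[i])
  } else {
    bep <- pts$precision[which.min(abs(d))]
  }
  list(points = pts, bep = bep)
}

#' Compare radiomics scores between the two label groups
#'
#' One-way ANOVA F-test of the LOOCV scores across the two classes (with
#' two groups this equals the pooled two-sided t-test, F = t^2), with the
#' Tukey HSD adjusted p-value for the pairwise contrast reported alongside.
#'
#' @inheritParams binary_metrics
#' @return Tibble with `anova_p` and `tukey_p`.
#' @export
compare_scores <- function(scores, labels) {
  g <- factor(labels)
  if (nlevels(g) != 2L || any(table(g) < 2L)) {
    stop("need two groups with at least 2 observations each", call. = FALSE)
  }
  fit <- stats::aov(scores ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tukey_p <- stats::TukeyHSD(fit)$g[1, "p adj"]
  tibble::tibble(anova_p = anova_p, tukey_p = tukey_p)
}

#' Sweep the number of top-ranked features
#'
#' Trains and LOOCV-evaluates the SVM on the top-1, top-2, ..., top-K
#' ranked features and records ACC, AUC, SENS and SPEC (percent) per k.
#' The best k maximizes AUC, breaking ties by higher ACC, then smaller k.
#'
#' @param table Feature table.
#' @param ranking [rank_by_src()] result.
#' @param k_max Largest feature count to try.
#' @param C,gamma SVM parameters.
#' @return Object of class `svm_sweep`: list with `metrics` (tibble, one
#'   row per k), `best_k`.
#' @export
sweep_feature_count <- function(table, ranking, k_max, C = 0.8, gamma = 1) {
  feats <- if (is.character(ranking)) ranking else ranking$feature
  k_max <- min(k_max, length(feats))
  metrics <- purrr::map_dfr(seq_len(k_max), function(k) {
    sc <- loocv_scores(table, feats, k, C = C, gamma = gamma)
    m <- binary_metrics(sc$score, sc$label)
    tibble::tibble(k = k, auc = 100 * auc_mw(sc$score, sc$label),
                   acc = m[["acc"]], sens = m[["sens"]], spec = m[["spec"]])
  })
  ord <- order(-metrics$auc, -metrics$acc, metrics$k)
  structure(list(metrics = metrics, best_k = metrics$k[ord[1]]),
            class = "svm_sweep")
}

#' @export
print.svm_sweep <- function(x, ...) {
  cat(sprintf("<svm_sweep> k = 1..%d, best k = %d (AUC %.2f%%)\n",
              max(x$metrics$k), x$best_k,
              x$metrics$auc[x$metrics$k == x$best_k]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.svm_sweep <- function(x, ...) x$metrics

#' @exportS3Method ggplot2::autoplot
autoplot.svm_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics, -"k",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed") +
    ggplot2::labs(x = "number of top-ranked features", y = "%", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Evaluate one model variant end to end
#'
#' LOOCV radiomics scores at a fixed feature count, with threshold-0
#' metrics, ROC/AUC with bootstrap CI, precision-recall curve with
#' break-even point, and the ANOVA/Tukey group comparison of the scores.
#'
#' @param table Feature table.
#' @param ranking [rank_by_src()] result.
#' @param k Number of top-ranked features.
#' @param C,gamma SVM parameters.
#' @param n_boot Bootstrap replicates for the AUC CI.
#' @return Object of class `model_report`.
#' @export
evaluate_model <- function(table, ranking, k, C = 0.8, gamma = 1, n_boot = 2000L) {
  sc <- loocv_scores(table, ranking, k, C = C, gamma = gamma)
  m <- binary_metrics(sc$score, sc$label)
  roc <- roc_auc(sc$score, sc$label, n_boot = n_boot)
  prc <- prc_bep(sc$score, sc$label)
  cmp <- compare_scores(sc$score, sc$label)
  structure(list(scores = sc, k = k, metrics = m, roc = roc, prc = prc,
                 anova = cmp), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> k = %d | AUC %.2f%% (CI %.3f-%.3f) ACC %.2f%% SENS %.2f%% SPEC %.2f%% BEP %.3f\n",
              x$k, 100 * x$roc$auc, x$roc$ci[1], x$roc$ci[2],
              x$metrics[["acc"]], x$metrics[["sens"]], x$metrics[["spec"]],
              x$prc$bep))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.model_report <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.model_report <- function(x, ...) {
  tibble::tibble(k = x$k, auc = 100 * x$roc$auc,
                 auc_ci_lo = x$roc$ci[1], auc_ci_hi = x$roc$ci[2],
                 acc = x$metrics[["acc"]], sens = x$metrics[["sens"]],
                 spec = x$metrics[["spec"]], bep = x$prc$bep,
                 anova_p = x$anova$anova_p)
}

#' @exportS3Method ggplot2::autoplot
autoplot.model_report <- function(object, which = c("roc", "prc"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(linetype = "dotted") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    title = sprintf("ROC (AUC %.2f%%)", 100 * object$roc$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$prc$points, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(linetype = "dotted") +
      ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(title = sprintf("Precision-recall (BEP %.3f)", object$prc$bep)) +
      ggplot2::theme_minimal()
  }
}
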