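blob_table <- function(n = 40, d = 2, sep = 3, seed = 0) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n / 2 * d, -sep / 2), n / 2, d),
               matrix(rnorm(n / 2 * d, sep / 2), n / 2, d))
  })
  colnames(X) <- paste0("f", seq_len(d))
  dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("P%02d", seq_len(n)),
                   label = rep(c(0L, 1L), each = n / 2)),
    tibble::as_tibble(as.data.frame(X)))
}

test_that("RBF SVM separates well-separated blobs and is label-symmetric", {
  tb <- blob_table(n = 40, sep = 6, seed = 0)
  X <- feature_matrix(tb)
  m <- train_svm(X, tb$label)
  sc <- decision_values(m, X)
  expect_true(all((sc > 0) == (tb$label == 1)))   # 100% training accuracy

  mflip <- train_svm(X, 1 - tb$label)
  expect_equal(decision_values(mflip, X), -sc, tolerance = 1e-6)

  # duplicating a non-support training point leaves the decision unchanged
  # (tight solver tolerance: the identity is exact only at the optimum)
  mt <- train_svm(X, tb$label, tolerance = 1e-9)
  sct <- decision_values(mt, X)
  far <- which.max(abs(sct))  # most interior point: never a support vector
  m2 <- train_svm(rbind(X, X[far, ]), c(tb$label, tb$label[far]), tolerance = 1e-9)
  expect_equal(decision_values(m2, X), sct, tolerance = 1e-6)

  expect_error(train_svm(X, rep(1, nrow(X))), "both classes")
  expect_error(train_svm(X[, 0], tb$label), "feature")
})

test_that("binary metrics reproduce confusion-table arithmetic", {
  # (TP, FN, TN, FP) = (13, 1, 12, 1)
  scores <- c(rep(1, 13), -1, rep(-1, 12), 1)
  labels <- c(rep(1, 14), rep(0, 13))
  m <- binary_metrics(scores, labels)
  expect_equal(m[["sens"]], 100 * 13 / 14, tolerance = 1e-10)  # 92.86%
  expect_equal(m[["spec"]], 100 * 12 / 13, tolerance = 1e-10)  # 92.31%
  expect_equal(m[["acc"]], 100 * 25 / 27, tolerance = 1e-10)

  expect_equal(unname(binary_metrics(c(-1, -1, 1, 1), c(0, 0, 1, 1))),
               c(100, 100, 100))
  allpos <- binary_metrics(rep(1, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(allpos[["sens"]], 100)
  expect_equal(allpos[["spec"]], 0)
})

test_that("AUC equals the brute-force concordant-pair count and is rank-invariant", {
  withr::with_seed(1, {
    for (rep in 1:5) {
      n <- sample(10:50, 1)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      scores <- round(rnorm(n), 1)   # rounding forces ties
      expect_equal(auc_mw(scores, labels), oracle_auc(scores, labels))
      # strictly monotone transform leaves AUC unchanged
      expect_equal(auc_mw(exp(2 * scores) + 1, labels), auc_mw(scores, labels))
      # pROC agreement
      expect_equal(auc_mw(scores, labels),
                   as.numeric(pROC::auc(labels, scores, levels = c(0, 1),
                                        direction = "<", quiet = TRUE)))
    }
  })
  expect_equal(auc_mw(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
})

test_that("ROC curve spans (0,0) to (1,1); null scores give chance AUC", {
  withr::with_seed(2, {
    labels <- rep(c(0, 1), each = 100)
    scores <- rnorm(200)   # independent of labels
    r <- roc_auc(scores, labels, n_boot = 200)
  })
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_gt(r$auc, 0.40); expect_lt(r$auc, 0.60)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])

  # CI behaves like a CI: covers the point estimate, width shrinks with n
  withr::with_seed(3, {
    small <- roc_auc(rnorm(40), rep(c(0, 1), 20), n_boot = 400)
    big <- roc_auc(rnorm(400), rep(c(0, 1), 200), n_boot = 400)
  })
  expect_lt(diff(big$ci), diff(small$ci))
})

test_that("precision-recall break-even point matches exhaustive threshold logic", {
  # perfect classifier
  expect_equal(prc_bep(c(1, 2, 3, 4), c(0, 0, 1, 1))$bep, 1)
  # all-equal scores: precision = prevalence at recall 1
  deg <- prc_bep(rep(0.3, 10), c(rep(0, 7), rep(1, 3)))
  expect_equal(deg$bep, 0.3)

  withr::with_seed(4, {
    for (rep in 1:10) {
      n <- sample(8:20, 1)
      labels <- rbinom(n, 1, 0.5); labels[1] <- 1
      scores <- rnorm(n)
      res <- prc_bep(scores, labels)
      # brute force: precision/recall at every threshold; bep must lie
      # within the precision interval of the sign-change bracket
      pr <- t(vapply(sort(unique(scores), decreasing = TRUE), function(t) {
        pred <- scores >= t
        c(prec = sum(pred & labels == 1) / sum(pred),
          rec = sum(pred & labels == 1) / sum(labels == 1))
      }, numeric(2)))
      d <- pr[, "prec"] - pr[, "rec"]
      i <- which(d[-length(d)] * d[-1] <= 0)[1]
      if (is.na(i)) {
        expect_equal(res$bep, pr[which.min(abs(d)), "prec"])
      } else {
        expect_gte(res$bep, min(pr[i:(i + 1), "prec"]) - 1e-12)
        expect_lte(res$bep, max(pr[i:(i + 1), "prec"]) + 1e-12)
      }
    }
  })
})

test_that("two-group score comparison equals the squared-t identity", {
  withr::with_seed(5, {
    s <- c(rnorm(50), rnorm(50))
    g <- rep(c(0, 1), each = 50)
  })
  cmp <- compare_scores(s, g)
  tt <- t.test(s[g == 1], s[g == 0], var.equal = TRUE)
  expect_equal(cmp$anova_p, tt$p.value, tolerance = 1e-10)
  expect_gt(cmp$anova_p, 0.05)            # null: no group difference
  expect_equal(cmp$tukey_p, cmp$anova_p, tolerance = 1e-8)

  withr::with_seed(6, s2 <- c(rnorm(50), rnorm(50) + 5))
  expect_lt(compare_scores(s2, g)$anova_p, 1e-3)

  expect_error(compare_scores(1:3, c(0, 1, 1)), "at least 2")
})

test_that("LOOCV yields one deterministic score per patient; separable data classify perfectly", {
  tb <- blob_table(n = 24, sep = 8, seed = 7)
  rk <- rank_by_src(tb)
  sc <- loocv_scores(tb, rk, k = 2)
  expect_identical(nrow(sc), 24L)
  expect_identical(sc$patient_id, tb$patient_id)
  expect_equal(binary_metrics(sc$score, sc$label)[["acc"]], 100)
  sc2 <- loocv_scores(tb, rk, k = 2)
  expect_identical(sc$score, sc2$score)
})

test_that("feature-count sweep records metrics per k and picks best by AUC", {
  tb <- blob_table(n = 20, sep = 4, seed = 8)
  # add noise features so ranking matters
  withr::with_seed(9, {
    noise <- matrix(rnorm(20 * 4), 20, 4)
  })
  colnames(noise) <- paste0("n", 1:4)
  tb <- dplyr::bind_cols(tb, tibble::as_tibble(as.data.frame(noise)))
  rk <- rank_by_src(tb)
  sw <- sweep_feature_count(tb, rk, k_max = 4)
  expect_identical(nrow(sw$metrics), 4L)
  expect_true(all(unlist(sw$metrics[, c("auc", "acc", "sens", "spec")]) >= 0 &
                    unlist(sw$metrics[, c("auc", "acc", "sens", "spec")]) <= 100))
  best <- sw$metrics[sw$metrics$k == sw$best_k, ]
  expect_equal(best$auc, max(sw$metrics$auc))

  sw1 <- sweep_feature_count(tb, rk, k_max = 1)
  expect_identical(sw1$best_k, 1L)

  # informative features help: planted cohorts, AUC(k = 3) >= AUC(k = 1)
  wins <- 0L
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 30
      y <- rep(c(0L, 1L), each = n / 2)
      ysc <- ifelse(y == 1, 1, -1)
      X <- matrix(rnorm(n * 20), n, 20)
      for (j in 1:3) X[, j] <- 0.6 * ysc + 0.8 * rnorm(n)
    })
    colnames(X) <- sprintf("g%02d", 1:20)
    tbp <- dplyr::bind_cols(
      tibble::tibble(patient_id = as.character(1:n), label = y),
      tibble::as_tibble(as.data.frame(X)))
    rkp <- rank_by_src(tbp)
    sp <- sweep_feature_count(tbp, rkp, k_max = 3)
    if (sp$metrics$auc[3] >= sp$metrics$auc[1]) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("model report assembles scores, curves and group test coherently", {
  tb <- blob_table(n = 20, sep = 4, seed = 10)
  rk <- rank_by_src(tb)
  rep_ <- evaluate_model(tb, rk, k = 2, n_boot = 100)
  g <- glance(rep_)
  expect_identical(nrow(g), 1L)
  expect_true(g$auc >= 0 && g$auc <= 100)
  expect_true(g$bep >= 0 && g$bep <= 1)
  expect_identical(nrow(tidy(rep_)), 20L)
  # ACC at threshold 0 consistent with the ROC point at that threshold
  sc <- rep_$scores
  fpr0 <- sum(sc$score > 0 & sc$label == 0) / sum(sc$label == 0)
  tpr0 <- sum(sc$score > 0 & sc$label == 1) / sum(sc$label == 1)
  expect_equal(rep_$metrics[["sens"]], 100 * tpr0)
  expect_equal(rep_$metrics[["spec"]], 100 * (1 - fpr0))
})
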