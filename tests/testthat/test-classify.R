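test_that("lesion aggregation takes medians ignoring missing values", {
  tab <- data.frame(lesion_id = c(1, 2, 2, 2), label = c("benign", rep("malignant", 3)),
                    Ktrans = c(0.3, 1, 2, 100), f = c(0.1, 0.2, NA, 0.4))
  out <- aggregate_lesions(tab, c("Ktrans", "f"))
  expect_equal(nrow(out), 2)
  expect_equal(out$Ktrans[out$lesion_id == 1], 0.3)    # median of one
  expect_equal(out$Ktrans[out$lesion_id == 2], 2)      # robust to the outlier
  expect_equal(out$f[out$lesion_id == 2], 0.3)         # NA ignored
  # permutation invariance
  perm <- aggregate_lesions(tab[c(3, 1, 4, 2), ], c("Ktrans", "f"))
  expect_equal(out, perm)
})

test_that("Spearman matrix matches the rank-then-Pearson brute force", {
  tab <- data.frame(a = c(3, 1, 4, 1.5, 9), b = c(2.7, 1.8, 2.8, 1.8, 3.1),
                    c = exp(c(3, 1, 4, 1.5, 9)))
  r <- spearman_matrix(tab, c("a", "b", "c"))
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "c"], 1)                         # monotone invariance
  brute <- cor(rank(tab$a), rank(tab$b))               # average ranks for ties
  expect_equal(r["a", "b"], brute)
  const <- spearman_matrix(cbind(tab, d = 1), c("a", "d"))
  expect_true(is.na(const["a", "d"]))
})

test_that("Fisher weights equal the closed-form pooled-covariance solution", {
  # 6-point, 2-feature instance; oracle computed from the definition
  tab <- data.frame(x1 = c(0, 1, 0.5, 3, 4, 3.5), x2 = c(0, 0.5, 1, 1, 0, 0.8),
                    label = rep(c("benign", "malignant"), each = 3))
  fit <- fit_lda(tab, c("x1", "x2"))
  mu0 <- colMeans(tab[1:3, 1:2]); mu1 <- colMeans(tab[4:6, 1:2])
  sigma <- (2 * cov(tab[1:3, 1:2]) + 2 * cov(tab[4:6, 1:2])) / 4
  oracle <- solve(sigma, mu1 - mu0)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-10)
  expect_equal(fit$lambda, 0)
})

test_that("isotropic pooled covariance aligns the discriminant with the mean difference", {
  # points at +/- e1, +/- e2 around each class mean: pooled covariance is
  # exactly isotropic, so w must be parallel to mu1 - mu0
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  tab <- as.data.frame(rbind(base, sweep(base, 2, c(5, 3), "+")))
  names(tab) <- c("x1", "x2")
  tab$label <- rep(c("benign", "malignant"), each = 4)
  w <- coef(fit_lda(tab, c("x1", "x2")))
  mu <- c(5, 3)
  cosang <- sum(w * mu) / sqrt(sum(w^2) * sum(mu^2))
  expect_lt(abs(cosang - 1), 1e-6)
})

test_that("a duplicated feature column takes the ridge path to finite weights", {
  set.seed(10)
  tab <- data.frame(x1 = rnorm(20), label = rep(c("benign", "malignant"), 10))
  tab$x1 <- tab$x1 + 2 * (tab$label == "malignant")
  tab$x2 <- tab$x1
  fit <- fit_lda(tab, c("x1", "x2"))
  expect_gt(fit$lambda, 0)
  expect_true(all(is.finite(coef(fit))))
})

test_that("LDA cross-checks against the reference implementation", {
  skip_if_not_installed("MASS")
  tab <- synthetic_table(25, sep_cols = c("Ktrans", "kep"), delta = 2)
  feats <- c("Ktrans", "kep", "f", "D")
  w <- coef(fit_lda(tab, feats))
  ref <- MASS::lda(as.matrix(tab[, feats]), grouping = tab$label)$scaling[, 1]
  cosang <- abs(sum(w * ref)) / sqrt(sum(w^2) * sum(ref^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("ROC matches exhaustive threshold enumeration and the Mann-Whitney identity", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.05, 0.6, 0.2)
  labels <- c("benign", "benign", "malignant", "malignant", "benign",
              "benign", "malignant", "malignant")
  roc <- roc_curve(scores, labels)
  pos <- labels == "malignant"
  for (i in seq_along(roc$thresholds)) {
    th <- roc$thresholds[i]
    expect_equal(roc$tpr[i], mean(scores[pos] >= th))
    expect_equal(roc$fpr[i], mean(scores[!pos] >= th))
  }
  # AUC = normalised Mann-Whitney U (ties count half)
  u <- mean(outer(scores[pos], scores[!pos],
                  function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc$auc, u)

  set.seed(21)
  for (rep in 1:5) {
    s <- round(rnorm(30), 1)
    l <- sample(c("benign", "malignant"), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(l)) < 2) next
    r <- roc_curve(s, l)
    p <- l == "malignant"
    u <- mean(outer(s[p], s[!p], function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, u)
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
})

test_that("ROC degenerate cases behave as documented", {
  sep <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c("benign", "malignant"), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$operating_point$tpr, 1)
  expect_equal(sep$operating_point$fpr, 0)

  flat <- roc_curve(rep(1, 8), rep(c("benign", "malignant"), 4))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_curve(1:4, rep("benign", 4)), "both classes")
})

test_that("ROC cross-checks against the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  s <- rnorm(50); l <- sample(c("benign", "malignant"), 50, replace = TRUE)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(l, s, levels = c("benign", "malignant"),
                                                         direction = "<"))))
  expect_equal(roc_curve(s, l)$auc, ref)
})

test_that("majority vote counts strictly above one half, ties to benign", {
  out <- majority_vote_lesions(c("malignant", "malignant", "benign"), rep(1, 3))
  expect_equal(out$predicted, "malignant")
  tie <- majority_vote_lesions(rep(c("malignant", "benign"), 2), rep(1, 4))
  expect_equal(tie$predicted, "benign")

  set.seed(12)
  for (rep in 1:10) {
    n <- sample(3:9, 1)
    pred <- sample(c("benign", "malignant"), n, replace = TRUE)
    res <- majority_vote_lesions(pred, rep(7, n), rep("malignant", n))
    expect_equal(res$predicted,
                 if (sum(pred == "malignant") / n > 0.5) "malignant" else "benign")
    expect_equal(res$percent_correct, 100 * mean(pred == "malignant"))
  }
})

test_that("LDA scores and ROC are invariant to affine feature rescaling", {
  tab <- synthetic_table(30, sep_cols = c("Ktrans", "f"), delta = 1.5, seed = 5)
  feats <- c("Ktrans", "f", "D", "kep")
  r1 <- roc_curve(predict(fit_lda(tab, feats), tab), tab$label)
  tab2 <- tab
  tab2$Ktrans <- 100 * tab$Ktrans - 7
  tab2$D <- 0.01 * tab$D + 3
  r2 <- roc_curve(predict(fit_lda(tab2, feats), tab2), tab2$label)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-10)
  expect_equal(r1$tpr, r2$tpr, tolerance = 1e-10)
})

test_that("feature-set comparison isolates the informative modality", {
  tab <- synthetic_table(40, sep_cols = c("Ktrans", "kep", "HR"), delta = 2.5, seed = 9)
  cmp <- compare_feature_sets(tab, "lesion")
  expect_gt(cmp$results$dce$roc$auc, 0.95)
  expect_lt(cmp$results$dw$roc$auc, 0.75)
  expect_gte(cmp$results$all$roc$auc,
             max(cmp$results$dce$roc$auc, cmp$results$dw$roc$auc) - 0.05)
  # determinism
  cmp2 <- compare_feature_sets(tab, "lesion")
  expect_equal(cmp$results$all$roc$auc, cmp2$results$all$roc$auc)
  expect_identical(cmp$results$all$misclassified, cmp2$results$all$misclassified)
})
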