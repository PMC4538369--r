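#' Names of the feature columns by modality
#'
#' The 23 analysis features: 3 diffusion (f, D_star, D), 17 model-free TIC
#' descriptors, and 3 kinetic (Ktrans, kep, vp). `"dce"` selects the 20
#' DCE-derived features, `"dw"` the 3 diffusion features, `"all"` all 23.
#'
#' @param set `"dce"`, `"dw"` or `"all"`.
#' @return Character vector of column names.
#' @export
feature_set <- function(set = c("all", "dce", "dw")) {
  set <- match.arg(set)
  dw <- c("f", "D_star", "D")
  dce <- c(tic_feature_names(), "Ktrans", "kep", "vp")
  switch(set, dw = dw, dce = dce, all = c(dw, dce))
}

#' Aggregate a voxel-level feature table to lesion level
#'
#' One row per lesion; every feature is the median over that lesion's
#' voxels, ignoring missing values. Lesions with zero voxels are excluded
#' with a warning.
#'
#' @param voxels data frame with `lesion_id`, `label` and feature columns.
#' @param features character vector of feature column names (default: all
#'   numeric columns other than identifiers).
#' @return Lesion-level data frame with `lesion_id`, `label` and the
#'   median features.
#' @export
aggregate_lesions <- function(voxels, features = NULL) {
  stopifnot(all(c("lesion_id", "label") %in% names(voxels)))
  if (is.null(features))
    features <- setdiff(names(voxels)[vapply(voxels, is.numeric, logical(1))],
                        c("lesion_id", "i", "j", "k", "rss", "n_clipped"))
  ids <- sort(unique(voxels$lesion_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- voxels[voxels$lesion_id == id, , drop = FALSE]
    meds <- vapply(features, function(f) {
      v <- sub[[f]][is.finite(sub[[f]])]
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
    cbind(data.frame(lesion_id = id, label = sub$label[1], n_voxels = nrow(sub)),
          as.data.frame(as.list(meds)))
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise Spearman correlation of features
#'
#' Spearman rank correlation between every pair of feature columns, with
#' pairwise-complete handling of missing values and average ranks for ties.
#' Constant columns yield `NA` for their pairs.
#'
#' @param table data frame containing the feature columns.
#' @param features character vector of columns to correlate (default: the
#'   23 analysis features present in the table).
#' @return Symmetric matrix of Spearman rho with unit diagonal.
#' @export
spearman_matrix <- function(table, features = intersect(feature_set("all"), names(table))) {
  x <- as.matrix(table[, features, drop = FALSE])
  suppressWarnings(r <- cor(x, method = "spearman", use = "pairwise.complete.obs"))
  diag(r) <- ifelse(colSums(is.finite(x)) > 0, 1, NA_real_)
  r
}

#' Fisher linear discriminant for benign vs malignant tables
#'
#' Two-class Fisher LDA: features are standardised internally (zero mean,
#' unit variance), the discriminant direction is
#' `w = Sigma_pooled^-1 (mu_mal - mu_ben)`, and a ridge term
#' `lambda = 1e-6 * trace(Sigma)` is added when the pooled covariance is
#' numerically singular. Weights are returned in original feature units;
#' scores increase with evidence for malignancy.
#'
#' @param table data frame with a binary `label` column
#'   (benign/malignant) and feature columns.
#' @param features character vector of feature columns to use.
#' @param ridge relative ridge factor applied to the trace when the pooled
#'   covariance is singular.
#' @return An object of class `lesion_lda`: `weights` (original units),
#'   `offset` (score threshold at the standardised class midpoint),
#'   `center`, `scale`, `w_std`, `features`, `lambda`. `predict` returns
#'   discriminant scores (or class labels with `type = "class"`).
#' @export
fit_lda <- function(table, features = feature_set("all"), ridge = 1e-6) {
  features <- intersect(features, names(table))
  y <- as.character(table$label)
  if (!all(y %in% c("benign", "malignant")))
    stop("label must be 'benign' or 'malignant'", call. = FALSE)
  if (min(table(y)) < 2 || length(unique(y)) < 2)
    stop("need at least 2 rows in each class", call. = FALSE)
  x <- as.matrix(table[, features, drop = FALSE])
  keep <- apply(is.finite(x), 2, all)
  if (!all(keep)) {
    # features with any missing value are dropped rather than imputed
    x <- x[, keep, drop = FALSE]
    features <- features[keep]
  }
  if (!ncol(x)) stop("no complete feature columns", call. = FALSE)
  centre <- colMeans(x)
  scl <- apply(x, 2, sd); scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scl, "/")
  mal <- y == "malignant"
  mu1 <- colMeans(xs[mal, , drop = FALSE]); mu0 <- colMeans(xs[!mal, , drop = FALSE])
  s1 <- cov(xs[mal, , drop = FALSE]); s0 <- cov(xs[!mal, , drop = FALSE])
  n1 <- sum(mal); n0 <- sum(!mal)
  sigma <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2)
  lambda <- 0
  w_std <- tryCatch({
    if (rcond(sigma) < 1e-10) stop("singular")
    solve(sigma, mu1 - mu0)
  }, error = function(e) {
    lambda <<- ridge * sum(diag(sigma))
    solve(sigma + diag(lambda, ncol(sigma)), mu1 - mu0)
  })
  weights <- w_std / scl
  offset <- sum(w_std * (mu1 + mu0) / 2) + sum(weights * centre)
  structure(list(weights = weights, offset = offset, center = centre,
                 scale = scl, w_std = w_std, mu = list(benign = mu0, malignant = mu1),
                 features = features, lambda = lambda),
            class = "lesion_lda")
}

#' @export
print.lesion_lda <- function(x, ...) {
  cat(sprintf("Fisher linear discriminant on %d features%s\n", length(x$features),
              if (x$lambda > 0) sprintf(" (ridge %.3g)", x$lambda) else ""))
  w <- sort(abs(x$w_std), decreasing = TRUE)
  cat("  largest standardised weights:",
      paste(sprintf("%s (%.3g)", names(head(w, 5)), head(w, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.lesion_lda <- function(object, ...) object$weights

#' @export
predict.lesion_lda <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  score <- drop(x %*% object$weights) - object$offset
  if (type == "score") return(score)
  ifelse(score > 0, "malignant", "benign")
}

#' Empirical ROC curve with an imbalance-aware operating point
#'
#' Full empirical ROC over all score thresholds (prediction rule:
#' `score >= threshold` is malignant), AUC by the trapezoidal rule, and an
#' operating point chosen by maximising the prevalence-weighted Youden
#' index `J_w = w * TPR - (1 - w) * FPR`. By default `w` is the empirical
#' prevalence of the malignant class, which favours sensitivity when
#' malignant cases are the minority-cost class of a screening protocol.
#'
#' @param scores numeric discriminant scores (higher = more malignant).
#' @param labels labels, `"benign"`/`"malignant"` (or logical, TRUE =
#'   malignant).
#' @param prevalence_weight weight `w` in the Youden criterion; default the
#'   empirical malignant prevalence.
#' @return An object of class `roc_result`: `thresholds`, `tpr`, `fpr`
#'   (monotone from (0,0) to (1,1)), `auc`, and `operating_point`
#'   (threshold, tpr, fpr, j).
#' @export
roc_curve <- function(scores, labels, prevalence_weight = NULL) {
  pos <- if (is.logical(labels)) labels else as.character(labels) == "malignant"
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  stopifnot(length(scores) == length(pos), all(is.finite(scores)))
  w <- if (is.null(prevalence_weight)) mean(pos) else prevalence_weight
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) mean(scores[pos] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(scores[!pos] >= th), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  j <- w * tpr - (1 - w) * fpr
  best <- which.max(j)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 prevalence_weight = w,
                 operating_point = list(threshold = thr[best], tpr = tpr[best],
                                        fpr = fpr[best], j = j[best])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf("ROC: AUC = %.3f; operating point TPR = %.3f, FPR = %.3f (w = %.2f)\n",
              x$auc, op$tpr, op$fpr, x$prevalence_weight))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  op <- x$operating_point
  graphics::points(op$fpr, op$tpr, col = 2, pch = 19)
  invisible(x)
}

#' Majority-vote lesion classification from voxel predictions
#'
#' A lesion is labelled malignant if and only if strictly more than 50% of
#' its voxels are predicted malignant (an exact 50/50 split is benign).
#' When true labels are supplied, the per-lesion percentage of voxels whose
#' prediction matches the lesion's true label is also reported.
#'
#' @param predictions per-voxel predicted labels
#'   (`"benign"`/`"malignant"`).
#' @param lesion_id per-voxel lesion id.
#' @param true_labels optional per-voxel true labels (constant within a
#'   lesion).
#' @return Data frame with one row per lesion: `lesion_id`, `n_voxels`,
#'   `frac_malignant`, `predicted`, and (if truth given) `label` and
#'   `percent_correct`.
#' @export
majority_vote_lesions <- function(predictions, lesion_id, true_labels = NULL) {
  stopifnot(length(predictions) == length(lesion_id))
  ids <- sort(unique(lesion_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- lesion_id == id
    frac <- mean(predictions[sel] == "malignant")
    row <- data.frame(lesion_id = id, n_voxels = sum(sel), frac_malignant = frac,
                      predicted = if (frac > 0.5) "malignant" else "benign")
    if (!is.null(true_labels)) {
      row$label <- as.character(true_labels[sel][1])
      row$percent_correct <- 100 * mean(predictions[sel] == row$label)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Compare DCE-only, DW-only and combined feature sets
#'
#' For each requested feature set, fits the Fisher discriminant at the
#' requested level, computes the ROC with the imbalance-aware operating
#' point, classifies at that threshold, and (at voxel level) applies the
#' per-lesion majority vote. Reports which lesions each set misclassifies.
#'
#' @param table feature table (voxel- or lesion-level) with `lesion_id`,
#'   `label` and the 23 feature columns.
#' @param level `"voxel"` or `"lesion"`; voxel-level adds the majority-vote
#'   lesion summary.
#' @param sets subset of `c("dce", "dw", "all")`.
#' @param prevalence_weight passed to [roc_curve()].
#' @return A list of class `feature_set_comparison`: per set `lda`, `roc`,
#'   `predicted`, `lesions` (majority vote / lesion table with
#'   correctness), `misclassified` (lesion ids).
#' @export
compare_feature_sets <- function(table, level = c("lesion", "voxel"),
                                 sets = c("dce", "dw", "all"),
                                 prevalence_weight = NULL) {
  level <- match.arg(level)
  res <- lapply(sets, function(s) {
    lda <- fit_lda(table, feature_set(s))
    scores <- predict(lda, table)
    roc <- roc_curve(scores, table$label, prevalence_weight)
    pred <- ifelse(scores >= roc$operating_point$threshold, "malignant", "benign")
    if (level == "voxel") {
      les <- majority_vote_lesions(pred, table$lesion_id, table$label)
      mis <- les$lesion_id[les$predicted != les$label]
    } else {
      les <- data.frame(lesion_id = table$lesion_id, label = table$label,
                        predicted = pred,
                        percent_correct = 100 * (pred == table$label))
      mis <- les$lesion_id[les$predicted != les$label]
    }
    list(set = s, lda = lda, roc = roc, predicted = pred,
         lesions = les, misclassified = mis)
  })
  names(res) <- sets
  structure(list(results = res, level = level), class = "feature_set_comparison")
}

#' @export
print.feature_set_comparison <- function(x, ...) {
  cat(sprintf("Feature-set comparison (%s level)\n", x$level))
  for (r in x$results) {
    cat(sprintf("  %-4s AUC = %.3f, TPR = %.2f, FPR = %.2f, misclassified lesions: %d\n",
                r$set, r$roc$auc, r$roc$operating_point$tpr,
                r$roc$operating_point$fpr, length(r$misclassified)))
  }
  invisible(x)
}
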