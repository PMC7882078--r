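#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (FP + TN)`,
#' `accuracy = (TN + TP) / (TP + FP + TN + FN)`.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + fn == 0 || fp + tn == 0) {
    stop("metrics undefined: one class has no evaluated samples")
  }
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (fp + tn),
       accuracy = (tn + tp) / (tp + fp + tn + fn))
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' The probability that a random positive outranks a random negative, with
#' tied scores contributing 1/2; identical to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores numeric vector.
#' @param labels vector coercible to 0/1 (1 = positive); both classes must
#'   be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.stratified_folds <- function(groups, folds) {
  fold <- integer(length(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

#' Cross-validated SVM evaluation of a miRNA panel
#'
#' Stratified k-fold cross-validation of a radial-kernel support vector
#' machine (`e1071::svm`, cost 1, kernel width `1 / n_features`, the
#' package defaults) on the expression of the panel features. Out-of-fold
#' decision values are pooled for the AUC; out-of-fold hard predictions
#' are pooled into a confusion table for sensitivity, specificity and
#' accuracy (disease = positive class). Per-fold AUC averaging is
#' available via `pool_auc = FALSE`.
#'
#' @param study an [expression_study].
#' @param panel character vector of 1-2 (or more) feature ids.
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses
#'   `1 / length(panel)`.
#' @param pool_auc pool decision values across folds (default) or average
#'   per-fold AUCs.
#' @return list of class `panel_eval`: `panel`, `sensitivity`,
#'   `specificity`, `accuracy`, `auc`, and the pooled `counts` (tp, tn,
#'   fp, fn).
#' @export
cv_svm_eval <- function(study, panel, folds = 5, seed = 1, cost = 1,
                        gamma = NULL, pool_auc = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  missing_feat <- setdiff(panel, rownames(study$values))
  if (length(missing_feat) > 0) {
    stop("panel feature(s) not in the matrix: ",
         paste(missing_feat, collapse = ", "))
  }
  x <- t(study$values[panel, , drop = FALSE])
  if (any(apply(x, 2, stats::sd) == 0)) {
    warning("constant panel feature(s); SVM scaling disabled for them")
  }
  y <- study$groups
  if (is.null(gamma)) gamma <- 1 / length(panel)
  set.seed(as.integer(seed))
  fold <- .stratified_folds(y, folds)
  dec <- numeric(length(y))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_auc <- numeric(folds)
  for (k in seq_len(folds)) {
    test <- fold == k
    fit <- e1071::svm(x[!test, , drop = FALSE], y[!test],
                      kernel = "radial", cost = cost, gamma = gamma)
    pr <- stats::predict(fit, x[test, , drop = FALSE],
                         decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # e1071 signs decision values toward the class named first in the
    # column label; orient so larger = disease
    first <- strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1]
    if (first != "disease") dv <- -dv
    dec[test] <- dv
    pred[test] <- pr
    fold_auc[k] <- roc_auc(dv, y[test] == "disease")
  }
  tp <- sum(pred == "disease" & y == "disease")
  tn <- sum(pred == "control" & y == "control")
  fp <- sum(pred == "disease" & y == "control")
  fn <- sum(pred == "control" & y == "disease")
  metrics <- confusion_metrics(tp, tn, fp, fn)
  auc <- if (pool_auc) roc_auc(dec, y == "disease") else mean(fold_auc)
  structure(c(list(panel = panel), metrics,
              list(auc = auc, counts = c(tp = tp, tn = tn, fp = fp, fn = fn))),
            class = "panel_eval")
}

#' @export
print.panel_eval <- function(x, ...) {
  cat(sprintf("panel [%s]: sens %.3f spec %.3f acc %.3f AUC %.3f\n",
              paste(x$panel, collapse = " + "), x$sensitivity,
              x$specificity, x$accuracy, x$auc))
  invisible(x)
}

#' Dataset-level ROC AUC of a single miRNA used directly as a score
#'
#' The feature's expression is the ranking score, oriented so the AUC is
#' at least 0.5 on the supplied (training) data; the chosen orientation is
#' returned so it can be frozen and reapplied to validation data.
#'
#' @param study an [expression_study].
#' @param mirna feature id.
#' @param orientation `+1`/`-1` to force a previously chosen orientation,
#'   or `NULL` to choose it from this data.
#' @return list with `auc` and `orientation`.
#' @export
direct_roc <- function(study, mirna, orientation = NULL) {
  stopifnot(mirna %in% rownames(study$values))
  sc <- study$values[mirna, ]
  lab <- study$groups == "disease"
  if (is.null(orientation)) {
    orientation <- if (roc_auc(sc, lab) >= 0.5) 1 else -1
  }
  list(auc = roc_auc(orientation * sc, lab), orientation = orientation)
}

#' Evaluate all single and paired miRNA panels
#'
#' Runs [cv_svm_eval] on every singleton and every unordered pair of the
#' candidate features. Each pair additionally reports the mean of its two
#' members' singleton AUCs, the usual baseline for judging whether the
#' combination adds discriminating power.
#'
#' @param study an [expression_study].
#' @param candidates character vector of >= 2 feature ids.
#' @param folds,seed,cost,gamma,pool_auc passed to [cv_svm_eval].
#' @return data.frame sorted by AUC descending with columns `panel`,
#'   `n_markers`, `sensitivity`, `specificity`, `accuracy`, `auc`,
#'   `mean_single_auc` (NA for singletons).
#' @export
panel_search <- function(study, candidates, folds = 5, seed = 1, cost = 1,
                         gamma = NULL, pool_auc = TRUE) {
  stopifnot(length(candidates) >= 2)
  singles <- lapply(candidates, function(m) {
    cv_svm_eval(study, m, folds = folds, seed = seed, cost = cost,
                gamma = gamma, pool_auc = pool_auc)
  })
  names(singles) <- candidates
  pairs <- utils::combn(candidates, 2, simplify = FALSE)
  rows <- lapply(c(singles, lapply(pairs, function(p) {
    ev <- cv_svm_eval(study, p, folds = folds, seed = seed, cost = cost,
                      gamma = gamma, pool_auc = pool_auc)
    ev$mean_single_auc <- mean(c(singles[[p[1]]]$auc, singles[[p[2]]]$auc))
    ev
  })), function(ev) {
    data.frame(panel = paste(ev$panel, collapse = "/"),
               n_markers = length(ev$panel),
               sensitivity = ev$sensitivity, specificity = ev$specificity,
               accuracy = ev$accuracy, auc = ev$auc,
               mean_single_auc = if (is.null(ev$mean_single_auc)) NA_real_
                                 else ev$mean_single_auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc, out$panel), , drop = FALSE]
}
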