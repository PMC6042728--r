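# Confusion-matrix metrics, ROC/AUC, threshold selection, the five-fold
# cross-validation harness and per-class composition summaries.

#' Confusion-matrix performance metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/(TP+TN+FP+FN), and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), reported on
#' \[-1, 1\] and defined as 0 when any factor of the denominator is zero.
#' Fractions are kept at full precision; percentages are a display concern.
#'
#' @param TP,TN,FP,FN non-negative confusion counts.
#' @param threshold operating threshold the counts were taken at (recorded,
#'   optional).
#' @return an object of class `metrics_report`.
#' @export
#' @examples
#' confusion_metrics(TP = 20, TN = 425, FP = 0, FN = 95)
confusion_metrics <- function(TP, TN, FP, FN, threshold = NA_real_) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  TP <- as.double(TP); TN <- as.double(TN)
  FP <- as.double(FP); FN <- as.double(FN)
  if (TP + FN == 0) stop("no positives: sensitivity undefined")
  if (TN + FP == 0) stop("no negatives: specificity undefined")
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom2 == 0) 0 else (TP * TN - FP * FN) / sqrt(denom2)
  structure(list(TP = as.integer(TP), TN = as.integer(TN),
                 FP = as.integer(FP), FN = as.integer(FN),
                 sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP),
                 accuracy = (TP + TN) / (TP + TN + FP + FN),
                 MCC = mcc, threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report>  TP %d  FP %d  TN %d  FN %d%s\n",
              x$TP, x$FP, x$TN, x$FN,
              if (is.na(x$threshold)) "" else
                sprintf("  (threshold %.4g)", x$threshold)))
  cat(sprintf("  sensitivity %.4f  specificity %.4f  accuracy %.2f%%  MCC %.4f\n",
              x$sensitivity, x$specificity, 100 * x$accuracy, x$MCC))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps the decision threshold over all observed scores and reports the
#' (FPR, TPR) curve plus its trapezoidal area.  The AUC equals the
#' rank-based (Mann-Whitney) probability that a random positive outscores a
#' random negative, with ties counting one half.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels class labels: +1/-1, or logical, or a factor whose first
#'   level is the positive class.
#' @return an object of class `roc_result`: list with `points`
#'   (data.frame `fpr`, `tpr`, ordered) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- to_logical_labels(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  # Threshold sweep over unique score values (descending); ties grouped.
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(p)[grp_last] / n_pos)
  fpr <- c(0, cumsum(!p)[grp_last] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

to_logical_labels <- function(labels) {
  if (is.logical(labels)) labels
  else if (is.numeric(labels)) labels > 0
  else if (is.factor(labels)) labels == levels(labels)[1]
  else stop("labels must be logical, +1/-1 numeric, or a factor")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d threshold points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Plot method for ROC results
#'
#' @param x a [roc_auc()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Select an operating threshold maximizing accuracy
#'
#' Evaluates each candidate threshold (positive call iff `score >=
#' threshold`) and returns the grid value with the highest accuracy; ties
#' are broken towards higher specificity, then towards the larger
#' threshold.
#'
#' @param scores,labels as in [roc_auc()].
#' @param grid numeric vector of candidate thresholds.
#' @return the selected threshold (single numeric).
#' @export
select_threshold <- function(scores, labels, grid) {
  stopifnot(length(grid) >= 1L)
  pos <- to_logical_labels(labels)
  stats <- vapply(grid, function(t) {
    call <- scores >= t
    c(acc = mean(call == pos),
      spec = if (any(!pos)) mean(!call[!pos]) else 1)
  }, numeric(2))
  best <- order(-stats["acc", ], -stats["spec", ], -grid)[1]
  grid[best]
}

#' Five-fold cross-validation of a prediction method
#'
#' Splits the bundle with stratified folds and evaluates one of the four
#' methods with strict train/test separation:
#' \describe{
#'   \item{SVM}{tripeptide selection and model fitting are redone inside
#'     each training fold; test-fold peptides never influence the feature
#'     scheme.}
#'   \item{PSSM}{the frequency matrix is rebuilt from each training fold's
#'     positives.}
#'   \item{RES}{the regex library is a fixed external resource and is
#'     applied as given to each test fold.}
#'   \item{MIM}{by default the instance library is the training fold's
#'     positive peptides (a test positive is recovered only if its exact
#'     sequence recurs in training data); pass `config$instance_library`
#'     to use a fixed external library instead.}
#' }
#' Confusion counts are pooled (micro-averaged) across the five test folds;
#' continuous methods (SVM, PSSM) additionally return a pooled ROC.
#'
#' @param bundle a [dataset_bundle()].
#' @param method `"SVM"`, `"PSSM"`, `"RES"` or `"MIM"`.
#' @param config method options: `components`, `hyperparameters`,
#'   `svm_threshold` (default 0), `pssm_mode` (default
#'   `"background_odds"`), `pssm_threshold` (default 1), `regex_library`,
#'   `instance_library`.
#' @param n_folds folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return an object of class `cv_result`: list with `metrics`
#'   ([confusion_metrics()]), `roc` ([roc_auc()] or `NULL`), `scores`,
#'   `labels`, `method`, `n_folds`.
#' @export
cross_validate <- function(bundle, method = c("SVM", "PSSM", "RES", "MIM"),
                           config = list(), n_folds = 5L, seed = NULL) {
  method <- match.arg(method)
  folds <- make_folds(bundle, n_folds, seed)
  scores <- numeric(0)
  labels <- logical(0)
  calls <- logical(0)
  threshold <- switch(method,
                      SVM = config$svm_threshold %||% 0,
                      PSSM = config$pssm_threshold %||% 1,
                      NA_real_)
  for (k in seq_len(n_folds)) {
    tr_pos <- bundle$positives[folds$pos_fold != k, , drop = FALSE]
    tr_neg <- bundle$negatives[folds$neg_fold != k, , drop = FALSE]
    te_pos <- bundle$positives[folds$pos_fold == k, , drop = FALSE]
    te_neg <- bundle$negatives[folds$neg_fold == k, , drop = FALSE]
    te_seq <- c(te_pos$sequence, te_neg$sequence)
    te_ct <- c(te_pos$is_c_terminal, te_neg$is_c_terminal)
    lab <- rep(c(TRUE, FALSE), c(nrow(te_pos), nrow(te_neg)))
    if (method == "SVM") {
      tr <- dataset_bundle(bundle$domain_class, tr_pos, tr_neg,
                           bundle$balance_mode)
      comps <- config$components %||% default_components(bundle$domain_class)
      sel <- if ("TPC" %in% comps)
        select_overrepresented_tripeptides(tr_pos$sequence) else character(0)
      scheme <- feature_scheme(comps, sel)
      model <- svm_train(tr, scheme, config$hyperparameters %||% list())
      sc <- svm_decision(model, te_seq, te_ct)
      cl <- sc >= threshold
    } else if (method == "PSSM") {
      mat <- build_pssm(tr_pos$sequence,
                        L = domain_window(bundle$domain_class),
                        mode = config$pssm_mode %||% "background_odds",
                        domain_class = bundle$domain_class)
      sc <- predict(mat, te_seq)
      cl <- sc >= threshold
    } else if (method == "RES") {
      lib <- config$regex_library %||% default_regex_library(bundle$domain_class)
      cl <- vapply(te_seq, res_classify, logical(1), library = lib,
                   USE.NAMES = FALSE)
      sc <- as.numeric(cl)
    } else {
      lib <- config$instance_library %||%
        instance_library(tr_pos$sequence, bundle$domain_class)
      cl <- vapply(te_seq, mim_classify, logical(1), library = lib,
                   USE.NAMES = FALSE)
      sc <- as.numeric(cl)
    }
    scores <- c(scores, sc)
    labels <- c(labels, lab)
    calls <- c(calls, cl)
  }
  metrics <- confusion_metrics(TP = sum(calls & labels),
                               TN = sum(!calls & !labels),
                               FP = sum(calls & !labels),
                               FN = sum(!calls & labels),
                               threshold = threshold)
  roc <- if (method %in% c("SVM", "PSSM")) roc_auc(scores, labels) else NULL
  structure(list(metrics = metrics, roc = roc, scores = scores,
                 labels = labels, method = method, n_folds = n_folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold cross-validation (pooled)\n",
              x$method, x$n_folds))
  print(x$metrics)
  if (!is.null(x$roc)) cat(sprintf("  AUC %.4f\n", x$roc$auc))
  invisible(x)
}

#' Mean amino-acid composition per ligand class
#'
#' @param class_sets named list mapping a class name to a character vector
#'   of peptides.
#' @return numeric matrix, one row per class, 20 columns in fixed
#'   alphabetical amino-acid order; entries are mean AAC percentages.
#' @export
#' @examples
#' composition_summary(list(SH3 = c("PPRPLP", "KPPPVP"), bg = c("ACDEFG")))
composition_summary <- function(class_sets) {
  stopifnot(length(class_sets) > 0L, all(lengths(class_sets) > 0L))
  out <- t(vapply(class_sets, function(peps)
    colMeans(t(vapply(peps, aac, numeric(20L)))), numeric(20L)))
  colnames(out) <- AA_ALPHABET
  out
}
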