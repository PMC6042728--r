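# RBF-kernel support vector machine over compositional features.
# The margin-maximising fit itself is delegated to libsvm via e1071;
# feature encoding, class weighting, thresholding and tuning live here.

# Default feature components per domain: AAC+DPC+TPC for the 6-mer SH3/WW
# models, AAC+TPC plus the C-terminal flag for the 4-mer PDZ model (the
# best-performing combinations for each class).
DEFAULT_COMPONENTS <- list(SH3 = c("AAC", "DPC", "TPC"),
                           WW  = c("AAC", "DPC", "TPC"),
                           PDZ = c("AAC", "TPC", "CTERM"))

#' Default feature components for a domain class
#'
#' @param domain `"SH3"`, `"WW"` or `"PDZ"`.
#' @return character vector of feature-scheme components.
#' @export
default_components <- function(domain) {
  DEFAULT_COMPONENTS[[match.arg(domain, DOMAIN_CLASSES)]]
}

#' Train an RBF-kernel SVM ligand classifier
#'
#' Encodes the bundle's peptides with the given feature scheme and fits a
#' radial-basis-function support vector machine.  Class imbalance in
#' unbalanced bundles (roughly 1:4 to 1:2 positive:negative) is handled by
#' weighting the positive class by `n_neg / n_pos`; pass
#' `class_weights = c(pos = 1, neg = 1)` to disable.  The decision
#' threshold (default 0.00) is a free post-hoc parameter: changing it via
#' `model$threshold` never retrains.
#'
#' @param bundle a [dataset_bundle()].
#' @param scheme a [feature_scheme()]; default: the domain's default
#'   components with tripeptides selected from the bundle's positives.
#' @param hyperparameters list with elements `gamma` (RBF kernel width,
#'   default `1 / n_features`) and `cost` (regularization C, default 1).
#' @param threshold decision threshold on the margin score (default 0.00).
#' @param class_weights named vector `c(pos = , neg = )`, or `NULL` for the
#'   automatic `n_neg / n_pos` positive-class weight.
#' @param seed RNG seed (libsvm training is deterministic given the data;
#'   the seed fixes any upstream stochastic steps for reproducibility).
#' @return an object of class `svm_model`.
#' @export
svm_train <- function(bundle, scheme = NULL, hyperparameters = list(),
                      threshold = 0, class_weights = NULL, seed = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (nrow(bundle$positives) == 0L || nrow(bundle$negatives) == 0L)
    stop("training requires examples of both classes")
  if (is.null(scheme)) {
    comps <- default_components(bundle$domain_class)
    sel <- if ("TPC" %in% comps)
      select_overrepresented_tripeptides(bundle$positives$sequence)
    else character(0)
    scheme <- feature_scheme(comps, sel)
  }
  x <- rbind(
    encode_matrix(bundle$positives$sequence, scheme,
                  bundle$positives$is_c_terminal),
    encode_matrix(bundle$negatives$sequence, scheme,
                  bundle$negatives$is_c_terminal)
  )
  y <- factor(rep(c("pos", "neg"),
                  c(nrow(bundle$positives), nrow(bundle$negatives))),
              levels = c("pos", "neg"))
  # Kernel-width heuristic: 1 / (p * var(x)), which adapts to the 0-100
  # percentage scale of the composition features (gamma = 1/p would treat
  # them as unit-scaled and make the kernel vanish off-diagonal).
  gamma <- hyperparameters$gamma %||% {
    v <- stats::var(as.vector(x))
    1 / (ncol(x) * max(v, .Machine$double.eps))
  }
  cost <- hyperparameters$cost %||% 1
  if (is.null(class_weights)) {
    w <- if (bundle$balance_mode == "unbalanced")
      nrow(bundle$negatives) / nrow(bundle$positives) else 1
    class_weights <- c(pos = w, neg = 1)
  }
  fit <- with_seed(seed, e1071::svm(
    x, y, type = "C-classification", kernel = "radial",
    gamma = gamma, cost = cost, class.weights = class_weights,
    scale = FALSE
  ))
  # libsvm's decision values are signed towards its internal first label;
  # record whether that label is "pos" so scores are always pos-positive.
  flip <- fit$labels[1] != which(levels(y) == "pos")
  structure(list(fit = fit, scheme = scheme,
                 domain_class = bundle$domain_class,
                 threshold = threshold, gamma = gamma, cost = cost,
                 class_weights = class_weights, flip = flip,
                 n_pos = nrow(bundle$positives),
                 n_neg = nrow(bundle$negatives)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf(paste0("<svm_model> %s: RBF kernel (gamma = %.4g, C = %.4g), ",
                     "%s features (%d), trained on %d pos / %d neg, ",
                     "threshold %.2f\n"),
              x$domain_class, x$gamma, x$cost,
              paste(x$scheme$components, collapse = "+"),
              x$scheme$total_length, x$n_pos, x$n_neg, x$threshold))
  invisible(x)
}

#' SVM margin scores for query peptides
#'
#' @param model an [svm_train()] model.
#' @param peptides character vector of peptides of the model's window
#'   length.
#' @param is_c_terminal logical flag(s), recycled (see [encode()]).
#' @return numeric margin scores; `score >= model$threshold` is a positive
#'   call (boundary inclusive).
#' @export
svm_decision <- function(model, peptides, is_c_terminal = TRUE) {
  stopifnot(inherits(model, "svm_model"))
  L <- domain_window(model$domain_class)
  if (any(nchar(peptides) != L))
    stop("query peptides must have the model's window length ", L)
  x <- encode_matrix(peptides, model$scheme, is_c_terminal)
  pred <- predict(model$fit, x, decision.values = TRUE)
  dv <- as.vector(attr(pred, "decision.values"))
  if (model$flip) dv <- -dv
  dv
}

#' Predict method for SVM ligand models
#'
#' @param object an [svm_train()] model.
#' @param peptides character vector of query peptides.
#' @param is_c_terminal logical flag(s), recycled.
#' @param type `"score"` for margin scores, `"class"` for logical calls at
#'   the model's threshold.
#' @param ... unused.
#' @export
predict.svm_model <- function(object, peptides, is_c_terminal = TRUE,
                              type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- svm_decision(object, peptides, is_c_terminal)
  if (type == "score") s else s >= object$threshold
}

#' Grid-search SVM hyperparameters by cross-validated accuracy
#'
#' Evaluates every (gamma, cost) grid point by stratified `n_folds`-fold
#' cross-validation on the bundle and returns the point with the highest
#' mean CV accuracy.  Ties are broken towards smaller `cost` (weaker
#' fitting pressure), then smaller `gamma` (smoother kernel), then first in
#' grid order.
#'
#' @param bundle a [dataset_bundle()].
#' @param scheme a [feature_scheme()] (fixed across the grid; tripeptide
#'   selection is not re-run per fold here because the scheme is given).
#' @param grid data.frame with columns `gamma` and `cost`.
#' @param n_folds folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return list with the selected `gamma`, `cost` and the grid annotated
#'   with each point's mean CV `accuracy`.
#' @export
tune_hyperparameters <- function(bundle, scheme, grid, n_folds = 5L,
                                 seed = NULL) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("gamma", "cost") %in% names(grid)))
  folds <- make_folds(bundle, n_folds, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    total <- 0L
    for (k in seq_len(n_folds)) {
      tr <- dataset_bundle(bundle$domain_class,
                           bundle$positives[folds$pos_fold != k, , drop = FALSE],
                           bundle$negatives[folds$neg_fold != k, , drop = FALSE],
                           bundle$balance_mode)
      te_pos <- bundle$positives[folds$pos_fold == k, , drop = FALSE]
      te_neg <- bundle$negatives[folds$neg_fold == k, , drop = FALSE]
      model <- svm_train(tr, scheme,
                         list(gamma = grid$gamma[g], cost = grid$cost[g]))
      pp <- predict(model, te_pos$sequence, te_pos$is_c_terminal, "class")
      pn <- predict(model, te_neg$sequence, te_neg$is_c_terminal, "class")
      correct <- correct + sum(pp) + sum(!pn)
      total <- total + length(pp) + length(pn)
    }
    correct / total
  }, numeric(1))
  best <- order(-acc, grid$cost, grid$gamma)[1]
  list(gamma = grid$gamma[best], cost = grid$cost[best],
       grid = cbind(grid, accuracy = acc))
}

#' Default hyperparameter grid
#'
#' Kernel widths `2^-7 .. 2^3` crossed with costs `2^-3 .. 2^7` (steps of
#' 2 on the log2 scale).
#'
#' @return data.frame with columns `gamma`, `cost`.
#' @export
default_svm_grid <- function() {
  expand.grid(gamma = 2^seq(-7, 3, by = 2), cost = 2^seq(-3, 7, by = 2),
              KEEP.OUT.ATTRS = FALSE)
}
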