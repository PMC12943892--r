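#' Leave-one-subject-out folds
#'
#' One fold per distinct subject: that subject's trials form the test set
#' and every other subject's trials the training set, so held-out
#' generalization is measured across people rather than across trials.
#'
#' @param subject_ids Vector of subject identifiers, one per trial (or the
#'   distinct ids themselves).
#' @return List of folds, each a list with `train` and `test` subject ids.
#' @export
loso_folds <- function(subject_ids) {
  ids <- unique(subject_ids)
  if (length(ids) < 2L)
    stop("LOSO requires at least 2 distinct subjects")
  lapply(ids, function(s) list(train = setdiff(ids, s), test = s))
}

#' Confusion matrix from labels
#'
#' @param truth,predicted Integer class labels (1-based).
#' @param n_classes Number of classes; defaults to the max label seen.
#' @return `C x C` count matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, predicted,
                             n_classes = max(truth, predicted)) {
  stopifnot(length(truth) == length(predicted))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth))
    cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  cm
}

#' Classification metric suite
#'
#' Accuracy (`trace/total`), the generalized multiclass Matthews
#' correlation coefficient (the `R_k` covariance formula; 0 when the
#' denominator vanishes), and macro-averaged F1 (unweighted mean of
#' per-class F1, with classes lacking both instances and predictions
#' contributing 0).
#'
#' @param confusion `C x C` count matrix, rows = truth.
#' @return List with `accuracy`, `mcc`, `f1_macro`, all in `[-1, 1]` /
#'   `[0, 1]`.
#' @export
metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(confusion >= 0))
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is all zero")
  C <- nrow(confusion)
  acc <- sum(diag(confusion)) / total

  t_k <- rowSums(confusion)   # true occurrences per class
  p_k <- colSums(confusion)   # predicted occurrences per class
  c_tr <- sum(diag(confusion))
  num <- c_tr * total - sum(p_k * t_k)
  den <- sqrt(total^2 - sum(p_k^2)) * sqrt(total^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den

  f1 <- vapply(seq_len(C), function(k) {
    tp <- confusion[k, k]
    denom <- 2 * tp + (p_k[k] - tp) + (t_k[k] - tp)
    if (denom == 0) 0 else 2 * tp / denom
  }, 0)
  list(accuracy = acc, mcc = mcc, f1_macro = mean(f1))
}

#' Paired t-test on per-fold scores
#'
#' Two-sided paired t-test of fold-wise score differences, the standard way
#' of comparing two models evaluated on identical cross-validation folds.
#'
#' @param scores_a,scores_b Numeric vectors of equal length `>= 2`.
#' @return List with `t`, `p_value`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- scores_b - scores_a
  s <- stats::sd(d)
  if (s == 0)
    stop("all paired differences are identical; t statistic is degenerate")
  n <- length(d)
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       df = n - 1, mean_diff = mean(d))
}

#' LOSO cross-validated training and evaluation
#'
#' Trains one model per fold on all-but-one subject and evaluates on the
#' held-out subject, returning per-fold confusion counts and metrics plus
#' their mean and standard deviation. An identifier audit guarantees no
#' test-subject trial ever enters a training set.
#'
#' @param features Array `trials x channels x frames x bands`.
#' @param labels Integer class labels per trial.
#' @param subjects Subject id per trial.
#' @param config A [train_config()].
#' @return List with `folds` (per-fold data frames of subject, accuracy,
#'   mcc, f1), `mean`, `sd`, and `confusions`.
#' @export
loso_evaluate <- function(features, labels, subjects,
                          config = train_config()) {
  stopifnot(dim(features)[1L] == length(labels),
            length(labels) == length(subjects))
  folds <- loso_folds(subjects)
  n_classes <- max(labels)
  res <- vector("list", length(folds))
  confs <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    te <- subjects == folds[[f]]$test
    tr <- !te
    stopifnot(!any(subjects[tr] == folds[[f]]$test))  # leakage audit
    fit <- train_model(features[tr, , , , drop = FALSE], labels[tr],
                       config = config)
    pred <- predict_model(fit$model, features[te, , , , drop = FALSE])
    cm <- confusion_matrix(labels[te], pred$label, n_classes)
    m <- metrics(cm)
    confs[[f]] <- cm
    res[[f]] <- data.frame(subject = folds[[f]]$test,
                           accuracy = m$accuracy, mcc = m$mcc,
                           f1 = m$f1_macro)
  }
  tab <- do.call(rbind, res)
  list(folds = tab,
       mean = colMeans(tab[, c("accuracy", "mcc", "f1")]),
       sd = apply(tab[, c("accuracy", "mcc", "f1")], 2L, stats::sd),
       confusions = confs)
}
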