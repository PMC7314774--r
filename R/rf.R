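#' Random-forest group classification under repeated cross-validation
#'
#' Estimates how well microbiota composition predicts group membership
#' (e.g. childcare vs home care from POST samples) with a random forest
#' evaluated by repeated stratified k-fold cross-validation: per repeat,
#' samples are assigned to folds separately within each class, a forest
#' is trained on each training split only, and accuracy is measured on
#' the held-out folds. The mean over repeats is the reported accuracy;
#' chance level for a balanced two-class design is 0.5.
#'
#' @param X an [abundance_table()] (relative scale recommended) or
#'   numeric samples-by-features matrix.
#' @param labels factor (or coercible) of class labels, one per sample.
#' @param folds folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param n_trees trees per forest (default 500).
#' @param mtry variables tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed; fold assignment and forests are fully
#'   reproducible.
#' @return List of class `cv_accuracy`: `mean_accuracy`,
#'   `per_repeat_accuracies`, `folds`, `repeats`, `seed`.
#' @export
classify_groups <- function(X, labels, folds = 10L, repeats = 10L,
                            n_trees = 500L, mtry = NULL, seed = 1L) {
  Xm <- if (inherits(X, "abundance_table")) X$values else as.matrix(X)
  y <- factor(labels)
  if (nlevels(y) < 2L) stopf("need at least two classes")
  if (length(y) != nrow(Xm)) stopf("labels must match rows of X")
  cls_n <- table(y)
  if (any(cls_n < folds))
    stopf("class '%s' has %d samples, fewer than %d folds; reduce 'folds'",
          names(cls_n)[which.min(cls_n)], min(cls_n), folds)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(Xm))))
  acc <- numeric(repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_of <- integer(length(y))
      for (cl in levels(y)) {       # stratified assignment
        idx <- which(y == cl)
        fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      correct <- logical(length(y))
      for (f in seq_len(folds)) {
        test <- fold_of == f
        fit <- randomForest::randomForest(
          x = Xm[!test, , drop = FALSE], y = y[!test],
          ntree = n_trees, mtry = min(mtry, ncol(Xm)))
        pred <- stats::predict(fit, Xm[test, , drop = FALSE])
        correct[test] <- pred == y[test]
      }
      acc[r] <- mean(correct)
    }
  })
  structure(list(mean_accuracy = mean(acc), per_repeat_accuracies = acc,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "cv_accuracy")
}

#' @export
print.cv_accuracy <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV (%d repeats): mean accuracy %.1f%% (range %.1f-%.1f%%)\n",
              x$folds, x$repeats, 100 * x$mean_accuracy,
              100 * min(x$per_repeat_accuracies),
              100 * max(x$per_repeat_accuracies)))
  invisible(x)
}
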