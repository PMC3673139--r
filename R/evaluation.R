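# Evaluation protocol: confusion matrices, macro F-measure,
# per-class-probability MAE, repeated stratified holdout and stratified
# k-fold cross-validation.

#' Confusion matrix over the activity labels
#'
#' @param actual,predicted equal-length label vectors.
#' @param labels label ordering; defaults to the union of levels encountered,
#'   in [activity_labels()] order when applicable.
#' @return a `confusion_matrix`: integer matrix, rows = actual, columns =
#'   predicted.
#' @export
confusion_matrix <- function(actual, predicted, labels = NULL) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  }
  if (is.null(labels)) {
    seen <- unique(c(actual, predicted))
    labels <- if (all(seen %in% .activity_labels)) {
      .activity_labels
    } else {
      sort(seen)
    }
  }
  bad <- setdiff(unique(c(actual, predicted)), labels)
  if (length(bad)) {
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cm <- table(factor(actual, levels = labels),
              factor(predicted, levels = labels))
  out <- matrix(as.integer(cm), nrow = length(labels),
                dimnames = list(actual = labels, predicted = labels))
  structure(out, class = c("confusion_matrix", class(out)))
}

.as_confusion <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("`cm` must be a square confusion matrix", call. = FALSE)
  }
  if (any(cm < 0)) {
    stop("confusion counts must be nonnegative", call. = FALSE)
  }
  if (is.null(rownames(cm))) {
    dimnames(cm) <- list(actual = paste0("C", seq_len(nrow(cm))),
                         predicted = paste0("C", seq_len(ncol(cm))))
  }
  cm
}

#' Per-class precision, recall and F1
#'
#' For class c with true positives `T_p`, false positives `F_p` and false
#' negatives `F_n`: `P = T_p/(T_p+F_p)`, `R = T_p/(T_p+F_n)`,
#' `F1 = 2PR/(P+R)`; empty denominators give 0 by convention.
#'
#' @param cm a `confusion_matrix` (rows actual, columns predicted).
#' @return data frame with columns `label`, `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cm) {
  cm <- .as_confusion(cm)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  act_tot <- rowSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  p <- safe_div(tp, pred_tot)
  r <- safe_div(tp, act_tot)
  f1 <- safe_div(2 * p * r, p + r)
  data.frame(label = rownames(cm), precision = as.numeric(p),
             recall = as.numeric(r), f1 = as.numeric(f1),
             row.names = NULL)
}

#' Macro-averaged F-measure
#'
#' The unweighted mean of the per-class F1 scores -- the aggregation under
#' which published per-sport confusion matrices reproduce their printed
#' summary scores.
#'
#' @param cm a `confusion_matrix`.
#' @return scalar in [0, 1].
#' @export
macro_f_measure <- function(cm) {
  mean(precision_recall_f1(cm)$f1)
}

#' Mean absolute error of class-probability predictions
#'
#' `MAE = 1/(n k) * sum_i sum_c | p_ic - 1{c == actual_i} |` over the k
#' classes, the per-class-probability formulation used alongside F-measure
#' in classic data-mining toolkits.
#'
#' @param prob n-by-k matrix of predicted class probabilities, columns named
#'   by label; each row must sum to one (tolerance 1e-6).
#' @param actual length-n vector of true labels.
#' @return scalar in [0, 1].
#' @export
mean_absolute_error <- function(prob, actual) {
  prob <- as.matrix(prob)
  actual <- as.character(actual)
  if (nrow(prob) != length(actual)) {
    stop("`prob` and `actual` sizes differ", call. = FALSE)
  }
  if (is.null(colnames(prob)) || !all(actual %in% colnames(prob))) {
    stop("`prob` columns must be named and cover all actual labels",
         call. = FALSE)
  }
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  onehot <- matrix(0, nrow(prob), ncol(prob),
                   dimnames = dimnames(prob))
  onehot[cbind(seq_along(actual), match(actual, colnames(prob)))] <- 1
  mean(abs(prob - onehot))
}

.evaluation_report <- function(rep_results, metadata) {
  per_class_all <- lapply(rep_results, `[[`, "per_class")
  labels <- per_class_all[[1L]]$label
  avg <- per_class_all[[1L]]
  for (col in c("precision", "recall", "f1")) {
    avg[[col]] <- rowMeans(vapply(per_class_all, `[[`, numeric(length(labels)),
                                  col))
  }
  confusion <- Reduce(`+`, lapply(rep_results, `[[`, "confusion"))
  class(confusion) <- c("confusion_matrix", "matrix", "array")
  structure(
    list(confusion = confusion,
         per_class = avg,
         macro_f = mean(vapply(rep_results, `[[`, 0, "macro_f")),
         mae = mean(vapply(rep_results, `[[`, 0, "mae")),
         per_rep_macro_f = vapply(rep_results, `[[`, 0, "macro_f"),
         per_rep_mae = vapply(rep_results, `[[`, 0, "mae"),
         metadata = metadata),
    class = "evaluation_report")
}

.evaluate_split <- function(x, y, train_idx, spec) {
  fit <- sport_classifier(x[train_idx, , drop = FALSE], y[train_idx],
                          spec = spec)
  test_idx <- setdiff(seq_along(y), train_idx)
  prob <- predict(fit, x[test_idx, , drop = FALSE], type = "prob")
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                 levels = levels(y))
  cm <- confusion_matrix(y[test_idx], pred, labels = levels(y))
  pc <- precision_recall_f1(cm)
  list(confusion = cm, per_class = pc, macro_f = mean(pc$f1),
       mae = mean_absolute_error(prob, y[test_idx]))
}

.stratified_train_idx <- function(y, fraction) {
  unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    if (length(idx) < 2L) {
      stop(sprintf("class %s has fewer than 2 instances; cannot stratify", lv),
           call. = FALSE)
    }
    sample(idx, max(1L, round(fraction * length(idx))))
  }), use.names = FALSE)
}

.resolve_xy <- function(x, y) {
  if (is.null(y) && !is.null(x$label)) {
    y <- x$label
  }
  if (is.data.frame(x) && "label" %in% names(x)) {
    x <- feature_matrix(x)
  }
  list(x = .as_feature_frame(x), y = droplevels(as.factor(y)))
}

#' Repeated stratified holdout evaluation
#'
#' Draws `reps` independent stratified splits (per class, `train_fraction` of
#' the instances train the model and the rest test it), evaluates each, and
#' averages. Matches the protocol of taking two thirds of a balanced dataset
#' for training, re-randomizing ten times and averaging the scores.
#'
#' @param x feature table or feature data frame; @param y labels (see
#'   [sport_classifier()]).
#' @param spec a `classifier_spec` (or family name string).
#' @param reps number of random splits.
#' @param train_fraction fraction of each class used for training.
#' @param seed master seed; per-rep split and model seeds derive from it.
#' @return an `evaluation_report`: summed test confusion matrix, per-class
#'   precision/recall/F1 averaged over reps, `macro_f` and `mae` (rep means),
#'   the per-rep score vectors and run metadata.
#' @export
repeated_holdout <- function(x, y = NULL, spec = "svm_smo", reps = 10L,
                             train_fraction = 2 / 3, seed = 1L) {
  d <- .resolve_xy(x, y)
  if (is.character(spec)) {
    spec <- classifier_spec(spec, seed = seed)
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  results <- lapply(seq_len(reps), function(r) {
    set.seed(rep_seeds[r])
    train_idx <- .stratified_train_idx(d$y, train_fraction)
    rspec <- classifier_spec(spec$family, spec$hyperparameters,
                             seed = rep_seeds[r] %% 1000000L)
    .evaluate_split(d$x, d$y, train_idx, rspec)
  })
  .evaluation_report(results, list(
    protocol = "repeated_holdout", reps = reps,
    train_fraction = train_fraction, seed = seed,
    family = spec$family, n = length(d$y)))
}

#' Stratified k-fold cross-validation
#'
#' @inheritParams repeated_holdout
#' @param k number of folds; per class, fold sizes differ by at most one.
#' @return an `evaluation_report` averaged over the k folds.
#' @export
kfold_cv <- function(x, y = NULL, spec = "svm_smo", k = 10L, seed = 1L) {
  d <- .resolve_xy(x, y)
  if (is.character(spec)) {
    spec <- classifier_spec(spec, seed = seed)
  }
  set.seed(seed)
  fold <- integer(length(d$y))
  for (lv in levels(d$y)) {
    idx <- which(d$y == lv)
    if (length(idx) < k) {
      stop(sprintf("class %s has fewer instances than folds", lv),
           call. = FALSE)
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  results <- lapply(seq_len(k), function(f) {
    fspec <- classifier_spec(spec$family, spec$hyperparameters,
                             seed = spec$seed + f)
    .evaluate_split(d$x, d$y, which(fold != f), fspec)
  })
  .evaluation_report(results, list(
    protocol = "kfold_cv", k = k, seed = seed,
    family = spec$family, n = length(d$y)))
}

#' @export
print.evaluation_report <- function(x, digits = 3L, ...) {
  md <- x$metadata
  cat(sprintf("<evaluation_report> %s (%s), n = %d\n",
              md$protocol, md$family, md$n))
  cat(sprintf("  macro F-measure: %.*f   MAE: %.*f   (%d run%s)\n",
              digits, x$macro_f, digits, x$mae,
              length(x$per_rep_macro_f),
              if (length(x$per_rep_macro_f) == 1L) "" else "s"))
  invisible(x)
}

#' @export
summary.evaluation_report <- function(object, digits = 3L, ...) {
  print(object, digits = digits)
  cat("\nPer-class scores (averaged over runs):\n")
  print(cbind(object$per_class[1L],
              round(object$per_class[-1L], digits)), row.names = FALSE)
  cat("\nSummed test confusion matrix (rows = actual):\n")
  print(unclass(object$confusion))
  invisible(object)
}
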