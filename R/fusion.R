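# Maximum-confidence fusion of per-activity one-vs-rest models.
#
# One binary classifier is trained per activity label (that label against
# the rest); at prediction time the activity whose model reports the highest
# positive-class confidence wins, ties going to the lowest activity index.

#' Train a one-vs-rest fusion of per-activity classifiers
#'
#' @param x feature data frame or [feature_table()] (its `label` column is
#'   used as `y` when `y` is missing).
#' @param y label factor; every level must have at least 2 instances.
#' @param specs either a single `classifier_spec`/family name applied to all
#'   activities, or a named list giving one spec per label.
#' @param seed master seed; per-activity model seeds are derived from it when
#'   `specs` is a single family.
#' @return a `sport_fusion` with `predict` (`type = "class"` argmax label,
#'   `type = "confidence"` the raw per-label positive-class confidences,
#'   `type = "prob"` those confidences normalized to sum to one).
#' @export
sport_fusion <- function(x, y = NULL, specs = "svm_smo", seed = 1L) {
  if (is.null(y) && !is.null(x$label)) {
    y <- x$label
  }
  if (is.data.frame(x) && "label" %in% names(x)) {
    x <- feature_matrix(x)
  }
  x <- .as_feature_frame(x)
  y <- droplevels(as.factor(y))
  labels <- levels(y)
  if (length(labels) < 2L) {
    stop("fusion needs at least 2 activity labels", call. = FALSE)
  }
  counts <- table(y)
  if (any(counts < 2L)) {
    stop(sprintf("label(s) with fewer than 2 instances: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")),
         call. = FALSE)
  }
  if (inherits(specs, "classifier_spec") || is.character(specs)) {
    base <- if (is.character(specs)) {
      classifier_spec(specs, seed = seed)
    } else {
      specs
    }
    specs <- lapply(seq_along(labels), function(i) {
      classifier_spec(base$family, base$hyperparameters,
                      seed = base$seed + i - 1L)
    })
    names(specs) <- labels
  }
  if (!setequal(names(specs), labels)) {
    stop("`specs` must name exactly one classifier per label", call. = FALSE)
  }
  models <- lapply(labels, function(lab) {
    ybin <- factor(ifelse(y == lab, "pos", "rest"),
                   levels = c("rest", "pos"))
    sport_classifier(x, ybin, spec = specs[[lab]])
  })
  names(models) <- labels
  structure(list(labels = labels, models = models, n = nrow(x),
                 feature_names = names(x)),
            class = "sport_fusion")
}

#' Predict from a classifier fusion
#'
#' @param object a `sport_fusion`.
#' @param newdata feature data frame (columns matched by name).
#' @param type `"class"`, `"confidence"` or `"prob"`; see [sport_fusion()].
#' @param ... unused.
#' @return label factor, or a matrix with one column per activity.
#' @export
predict.sport_fusion <- function(object, newdata,
                                 type = c("class", "confidence", "prob"),
                                 ...) {
  type <- match.arg(type)
  conf <- vapply(object$labels, function(lab) {
    predict(object$models[[lab]], newdata, type = "prob")[, "pos"]
  }, numeric(nrow(as.data.frame(newdata))))
  conf <- matrix(conf, ncol = length(object$labels),
                 dimnames = list(NULL, object$labels))
  if (type == "confidence") {
    return(conf)
  }
  if (type == "prob") {
    tot <- rowSums(conf)
    prob <- conf / ifelse(tot > 0, tot, 1)
    prob[tot == 0, ] <- 1 / ncol(conf)
    return(prob)
  }
  factor(object$labels[max.col(conf, ties.method = "first")],
         levels = object$labels)
}

#' @export
print.sport_fusion <- function(x, ...) {
  fams <- unique(vapply(x$models, function(m) m$spec$family, ""))
  cat(sprintf(
    "<sport_fusion> %d one-vs-rest models (%s) over labels %s, %d training instances\n",
    length(x$models), paste(fams, collapse = "/"),
    paste(x$labels, collapse = ","), x$n))
  invisible(x)
}
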