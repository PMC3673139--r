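# Uniform training/prediction contract over five classifier families.
#
# Every family is fitted through the single entry point sport_classifier()
# and predicts through predict.sport_model(), which always returns a full
# per-class probability distribution (rows sum to one). Scale-sensitive
# families (SVM, MLP, k-NN) see features standardized with training-set
# mean/sd stored in the model; naive Bayes and the tree consume raw features.

.classifier_families <- c("svm_smo", "knn", "naive_bayes",
                          "logistic_model_tree", "mlp")

.family_defaults <- list(
  svm_smo = list(cost = 1),
  knn = list(k = 1L),
  naive_bayes = list(laplace = 0),
  logistic_model_tree = list(cp = 0.01, minbucket = 7L, min_leaf_fit = 10L,
                             decay = 1e-4, maxit = 200L),
  mlp = list(size = NULL, decay = 1e-4, maxit = 500L)
)

#' Specify a classifier
#'
#' @param family one of `"svm_smo"` (linear-kernel support vector machine,
#'   cost 1), `"knn"` (k-nearest neighbour, k = 1, Euclidean), `"naive_bayes"`
#'   (Gaussian likelihoods), `"logistic_model_tree"` (decision tree with
#'   multinomial-logistic leaf models) or `"mlp"` (one hidden layer of
#'   `(features + classes)/2` units, 500 epochs).
#' @param hyperparameters named list overriding the family defaults listed
#'   above; unknown names are rejected.
#' @param seed integer seed making training deterministic.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family = .classifier_families,
                            hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  defaults <- .family_defaults[[family]]
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s",
                 family, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v)
                if (is.null(v)) "auto" else format(v), ""),
              sep = "=", collapse = ", ")
  cat(sprintf("<classifier_spec> %s (%s), seed %d\n", x$family, hp, x$seed))
  invisible(x)
}

.as_feature_frame <- function(x) {
  x <- as.data.frame(x)
  if (!all(vapply(x, is.numeric, TRUE))) {
    stop("all feature columns must be numeric", call. = FALSE)
  }
  if (anyNA(x) || any(!vapply(x, function(col) all(is.finite(col)), TRUE))) {
    stop("features contain missing or non-finite values", call. = FALSE)
  }
  x
}

.standardize_fit <- function(x) {
  centre <- vapply(x, mean, 0)
  scale <- vapply(x, stats::sd, 0)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(centre = centre, scale = scale)
}

.standardize_apply <- function(x, std) {
  as.data.frame(scale(x, center = std$centre, scale = std$scale))
}

#' Train an activity classifier
#'
#' The single fitting entry point for all five classifier families. Either
#' give a feature table (from [feature_table()]) whose `label` column is the
#' response, or an explicit feature matrix `x` and label factor `y`.
#'
#' @param x numeric feature data frame/matrix, or a [feature_table()] data
#'   frame (its `label` column is then used as `y`).
#' @param y factor (or character) of class labels; ignored when `x` carries a
#'   `label` column and `y` is missing.
#' @param family,hyperparameters,seed forwarded to [classifier_spec()];
#'   alternatively pass a ready `spec`.
#' @param spec an explicit `classifier_spec`, overriding the previous three.
#' @return a `sport_model` with `print`, `summary` and `predict` methods.
#'   `predict(..., type = "prob")` returns the per-class probability matrix;
#'   `type = "class"` its argmax.
#' @examples
#' logs <- simulate_dataset(n_per_activity = 4, seed = 1)
#' feats <- feature_table(logs, "db4", level = 2, window_length = 5)
#' fit <- sport_classifier(feats, family = "naive_bayes", seed = 7)
#' table(predict(fit, feats), feats$label)
#' @export
sport_classifier <- function(x, y = NULL, family = "svm_smo",
                             hyperparameters = list(), seed = 1L,
                             spec = NULL) {
  if (is.null(spec)) {
    spec <- classifier_spec(family, hyperparameters, seed)
  }
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(y) && !is.null(x$label)) {
    y <- x$label
  }
  if (is.null(y)) {
    stop("labels `y` are required (or a `label` column in `x`)", call. = FALSE)
  }
  if (is.data.frame(x) && "label" %in% names(x)) {
    x <- feature_matrix(x)
  }
  x <- .as_feature_frame(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) {
    stop("`x` and `y` have different numbers of rows", call. = FALSE)
  }
  if (nlevels(y) < 2L) {
    stop("training needs at least 2 classes", call. = FALSE)
  }
  std <- NULL
  xs <- x
  if (spec$family %in% c("svm_smo", "knn", "mlp")) {
    std <- .standardize_fit(x)
    xs <- .standardize_apply(x, std)
  }
  set.seed(spec$seed)
  fit <- switch(
    spec$family,
    svm_smo = .fit_svm(xs, y, spec$hyperparameters),
    knn = list(x = as.matrix(xs), y = y, k = spec$hyperparameters$k),
    naive_bayes = e1071::naiveBayes(xs, y,
                                    laplace = spec$hyperparameters$laplace),
    logistic_model_tree = .fit_lmt(xs, y, spec$hyperparameters),
    mlp = .fit_mlp(xs, y, spec$hyperparameters))
  structure(
    list(spec = spec, fit = fit, levels = levels(y),
         feature_names = names(x), standardize = std, n = nrow(x)),
    class = "sport_model")
}

.fit_svm <- function(x, y, hp) {
  e1071::svm(x = as.matrix(x), y = y, kernel = "linear", cost = hp$cost,
             scale = FALSE, probability = TRUE)
}

.fit_mlp <- function(x, y, hp) {
  p <- ncol(x)
  k <- nlevels(y)
  size <- hp$size
  if (is.null(size)) {
    size <- max(1L, as.integer(floor((p + k) / 2)))
  }
  target <- nnet::class.ind(y)
  nnet::nnet(as.matrix(x), target, size = size, softmax = TRUE,
             decay = hp$decay, maxit = hp$maxit, trace = FALSE,
             MaxNWts = 100000L)
}

# Logistic model tree: an rpart classification tree whose leaves carry
# multinomial-logistic models fitted on the observations routed to them
# (falling back to Laplace-smoothed leaf class proportions for small or pure
# leaves).
.fit_lmt <- function(x, y, hp) {
  dat <- data.frame(.y = y, x, check.names = FALSE)
  tree <- rpart::rpart(.y ~ ., data = dat, method = "class",
                       control = rpart::rpart.control(
                         cp = hp$cp, minbucket = hp$minbucket, xval = 0L))
  leaf_rows <- which(tree$frame$var == "<leaf>")
  leaves <- lapply(leaf_rows, function(fr) {
    members <- which(tree$where == fr)
    ymem <- y[members]
    counts <- table(ymem)
    if (length(members) >= hp$min_leaf_fit && sum(counts > 0) > 1L) {
      sub <- data.frame(.y = droplevels(ymem),
                        x[members, , drop = FALSE], check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = sub, decay = hp$decay,
                            maxit = hp$maxit, trace = FALSE,
                            MaxNWts = 100000L)
      list(kind = "logistic", fit = fit, levels = levels(sub$.y))
    } else {
      prop <- (counts + 1) / sum(counts + 1)  # Laplace smoothing
      list(kind = "proportions", prob = as.numeric(prop),
           levels = names(counts))
    }
  })
  names(leaves) <- rownames(tree$frame)[leaf_rows]
  list(tree = tree, leaves = leaves)
}

# Route observations through an rpart tree to leaf node numbers. Features are
# all numeric and complete, so only primary splits are needed. Convention:
# splits[, "ncat"] == -1L sends x < cutpoint left, +1L sends x >= cutpoint
# left; children of node nn are 2*nn and 2*nn + 1.
.rpart_leaf <- function(tree, newx) {
  frame <- tree$frame
  node_of_row <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  nsplits <- ifelse(is_leaf, 0L, 1L + frame$ncompete + frame$nsurrogate)
  first_split <- cumsum(c(1L, nsplits[-length(nsplits)]))
  vapply(seq_len(nrow(newx)), function(i) {
    row <- 1L
    while (!is_leaf[row]) {
      sp <- tree$splits[first_split[row], ]
      var <- frame$var[row]
      goes_left <- if (sp[["ncat"]] < 0) {
        newx[i, var] < sp[["index"]]
      } else {
        newx[i, var] >= sp[["index"]]
      }
      child <- 2L * node_of_row[row] + if (goes_left) 0L else 1L
      row <- match(child, node_of_row)
    }
    node_of_row[row]
  }, 0L)
}

.predict_lmt <- function(fit, newx, levels) {
  leaf <- .rpart_leaf(fit$tree, newx)
  out <- matrix(0, nrow(newx), length(levels),
                dimnames = list(NULL, levels))
  for (nn in unique(leaf)) {
    rows <- which(leaf == nn)
    lf <- fit$leaves[[as.character(nn)]]
    if (lf$kind == "logistic") {
      pr <- stats::predict(lf$fit, newdata = newx[rows, , drop = FALSE],
                           type = "probs")
      if (is.null(dim(pr))) {  # two-class multinom returns a vector
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- lf$levels
      }
      out[rows, colnames(pr)] <- pr
    } else {
      out[rows, lf$levels] <- matrix(lf$prob, length(rows),
                                     length(lf$levels), byrow = TRUE)
    }
  }
  out
}

.predict_knn <- function(fit, newx) {
  train <- fit$x
  k <- fit$k
  lv <- levels(fit$y)
  out <- matrix(0, nrow(newx), length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(nrow(newx))) {
    d2 <- colSums((t(train) - newx[i, ])^2)
    nb <- order(d2)[seq_len(min(k, length(d2)))]
    votes <- table(fit$y[nb]) / length(nb)
    out[i, names(votes)] <- as.numeric(votes)
  }
  out
}

#' Predict from a trained activity classifier
#'
#' @param object a `sport_model`.
#' @param newdata feature data frame (feature tables are accepted; columns are
#'   matched to the training features by name, so order does not matter).
#' @param type `"prob"` for the per-class probability matrix (rows sum to
#'   one), `"class"` for the most probable label.
#' @param ... unused.
#' @return probability matrix or label factor.
#' @export
predict.sport_model <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    stop(sprintf("newdata lacks feature column(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  x <- .as_feature_frame(newdata[, object$feature_names, drop = FALSE])
  if (!is.null(object$standardize)) {
    x <- .standardize_apply(x, object$standardize)
  }
  prob <- switch(
    object$spec$family,
    svm_smo = {
      pr <- stats::predict(object$fit, as.matrix(x), probability = TRUE)
      attr(pr, "probabilities")[, object$levels, drop = FALSE]
    },
    knn = .predict_knn(object$fit, as.matrix(x)),
    naive_bayes = stats::predict(object$fit, x, type = "raw"),
    logistic_model_tree = .predict_lmt(object$fit, x, object$levels),
    mlp = {
      pr <- stats::predict(object$fit, as.matrix(x), type = "raw")
      colnames(pr) <- object$fit$lev %||% colnames(pr)
      pr
    })
  prob <- as.matrix(prob)[, object$levels, drop = FALSE]
  prob[prob < 0] <- 0
  prob <- prob / pmax(rowSums(prob), .Machine$double.eps)
  rownames(prob) <- NULL
  if (type == "prob") {
    return(prob)
  }
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sport_model <- function(x, ...) {
  cat(sprintf("<sport_model> %s trained on %d instances, %d features, %d classes\n",
              x$spec$family, x$n, length(x$feature_names), length(x$levels)))
  invisible(x)
}

#' @export
summary.sport_model <- function(object, ...) {
  print(object)
  print(object$spec)
  cat("classes:", paste(object$levels, collapse = ", "), "\n")
  cat("standardized features:",
      if (is.null(object$standardize)) "no" else "yes (train mean/sd)", "\n")
  invisible(object)
}
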