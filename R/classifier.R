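# SVM wrapper-fitness evaluator.  A maximum-margin binary classifier
# f(x) = w' phi(x) + b scores each sample; prediction is 1 iff the score is
# >= 0.  Features are standardized with training-split statistics only
# (filter-response features span orders of magnitude).  The in-loop fitness
# uses a linear kernel; the fine-tuned polynomial kernel is applied once
# selection has finished.  Backend: libsvm via e1071 with fixed cost C = 1.

#' Train a binary maximum-margin classifier
#'
#' @param X numeric training matrix (rows = samples), >= 1 column.
#' @param y binary labels (`0`/`1`) containing both classes.
#' @param spec a [kernel_spec()]; the polynomial kernel is
#'   `(<x, x'> / kernel_scale + kernel_offset) ^ poly_order`.
#' @return An object of class `stenosis_svm` holding the decision function
#'   and metadata (kernel spec, standardization statistics, training
#'   fingerprint).  Deterministic given identical inputs.
#' @export
train_classifier <- function(X, y, spec = kernel_spec("linear")) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (ncol(X) < 1L) {
    stop_ssfs("empty feature subset: X has zero columns",
              class = "classifier_error")
  }
  if (length(unique(y)) < 2L) {
    stop_ssfs("training labels contain a single class",
              class = "classifier_error")
  }
  stopifnot(inherits(spec, "kernel_spec"))
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  Xs <- scale(X, center = mu, scale = sd)
  yf <- factor(y, levels = c(0L, 1L))
  model <- if (spec$kind == "linear") {
    e1071::svm(Xs, yf, kernel = "linear", cost = 1, scale = FALSE)
  } else {
    e1071::svm(Xs, yf, kernel = "polynomial", degree = spec$poly_order,
               gamma = 1 / spec$kernel_scale, coef0 = spec$kernel_offset,
               cost = 1, scale = FALSE)
  }
  structure(list(
    model = model, center = mu, scale = sd, spec = spec,
    n_features = ncol(X),
    train_fingerprint = sum(X) + sum(y) # cheap identity check for metadata
  ), class = "stenosis_svm")
}

#' Predict with a trained classifier
#'
#' @param object a `stenosis_svm`.
#' @param newdata numeric matrix with the same columns as the training data.
#' @param type `"class"` for 0/1 labels, `"score"` for the signed decision
#'   value (positive scores predict class 1).
#' @param ... unused.
#' @return Integer labels or numeric scores; `label == 1` iff `score >= 0`.
#' @export
predict.stenosis_svm <- function(object, newdata, type = c("class", "score"),
                                 ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_ssfs("newdata has %d columns, expected %d", ncol(newdata),
              object$n_features, class = "classifier_error")
  }
  Xs <- scale(newdata, center = object$center, scale = object$scale)
  dv <- attr(stats::predict(object$model, Xs, decision.values = TRUE),
             "decision.values")
  # libsvm orients the decision value toward the first label of the pair;
  # flip so that positive scores always mean class 1
  pair <- colnames(dv)[1]
  score <- if (identical(pair, "1/0")) dv[, 1] else -dv[, 1]
  if (type == "score") as.numeric(score) else as.integer(score >= 0)
}

#' Serializable metadata of a trained classifier
#'
#' @param clf a `stenosis_svm`.
#' @return A list (kernel spec, feature count, support-vector count) safe to
#'   write as JSON; no model-weight portability is promised.
#' @export
classifier_metadata <- function(clf) {
  stopifnot(inherits(clf, "stenosis_svm"))
  list(kernel = unclass(clf$spec), n_features = clf$n_features,
       n_support_vectors = nrow(clf$model$SV))
}

#' Train on a feature subset and evaluate on a holdout split
#'
#' Trains on the training indices restricted to the masked columns and
#' evaluates on the requested holdout split, the wrapper step scored by the
#' selection fitness.
#'
#' @param ds a [labeled_dataset()].
#' @param part a [split_dataset()] partition.
#' @param mask logical/0-1 vector of length `n_features` with at least one
#'   bit set.
#' @param spec a [kernel_spec()].
#' @param eval_split `"validation"` (default, the in-loop holdout) or
#'   `"test"`.
#' @return A list with `confusion` ([confusion_counts()]) and `accuracy`.
#' @export
evaluate_subset <- function(ds, part, mask, spec = kernel_spec("linear"),
                            eval_split = c("validation", "test")) {
  eval_split <- match.arg(eval_split)
  stopifnot(inherits(ds, "labeled_dataset"), inherits(part, "partition_spec"))
  mask <- as.logical(mask)
  if (length(mask) != ncol(ds$features)) {
    stop_ssfs("mask length %d != number of features %d", length(mask),
              ncol(ds$features), class = "invalid_individual")
  }
  if (!any(mask)) {
    stop_ssfs("empty feature mask", class = "invalid_individual")
  }
  hold <- if (eval_split == "validation") part$validation_idx else
    part$test_idx
  clf <- train_classifier(ds$features[part$train_idx, mask, drop = FALSE],
                          ds$labels[part$train_idx], spec)
  pred <- predict(clf, ds$features[hold, mask, drop = FALSE])
  cm <- confusion(ds$labels[hold], pred)
  list(confusion = cm, accuracy = (cm$tp + cm$tn) / length(hold))
}

#' Memoized wrapper-fitness closure
#'
#' Returns `f(bits) -> fitness in [0, 1]` combining holdout accuracy (linear
#' kernel on the validation split) with the feature decreasing rate under
#' the configured weights.  Evaluations are cached by bit pattern, and an
#' empty mask scores 0 (invalid individual) rather than erroring, so the
#' optimizer loop cannot be derailed.
#'
#' @param ds a [labeled_dataset()].
#' @param part a [split_dataset()] partition.
#' @param cfg a [run_config()] (weights are taken from it).
#' @return A function of a bit vector; its environment carries the cache
#'   (`n_evals` reports unique evaluations).
#' @export
wrapper_fitness <- function(ds, part, cfg = run_config()) {
  cache <- new.env(parent = emptyenv())
  w <- cfg$weights
  n_total <- ncol(ds$features)
  fn <- function(bits) {
    bits <- as.logical(bits)
    if (!any(bits)) return(0)
    key <- rawToChar(as.raw(44L + bits)) # ','/'-' pattern, cheap unique key
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    acc <- evaluate_subset(ds, part, bits, kernel_spec("linear"),
                           "validation")$accuracy
    val <- fitness_score(acc, feature_decreasing_rate(sum(bits), n_total), w)
    cache[[key]] <- val
    val
  }
  attr(fn, "cache") <- cache
  fn
}
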