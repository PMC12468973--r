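# Linear wrapper classifier used by the fitness function and by the exact
# Shapley refinement. A closed-form L2-regularized least-squares classifier
# on +/-1 targets (one-vs-rest for >2 classes): linear and max-margin-like,
# deterministic, and ~microseconds per fit, which the wrapper loop
# (population x iterations x CV folds evaluations) requires.

#' Fit the linear fitness classifier
#'
#' Regularized least-squares linear classifier: for each class, weights
#' solve `(X'X + lambda I) w = X' y` with `y` coded +1/-1 (one-vs-rest when
#' more than two classes). Features are standardized internally with
#' training statistics.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Integer class labels (0-based).
#' @param lambda Ridge penalty. Default 1.
#' @return Object of class `linear_clf` with per-class weights, intercepts,
#'   and the training standardization.
#' @export
fit_linear_clf <- function(x, y, lambda = 1) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("Training data has a single class.")
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0 | is.na(sg)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  d <- ncol(xs)
  gram <- crossprod(xs) + diag(lambda, d)
  w <- matrix(0, d, length(classes))
  b <- numeric(length(classes))
  for (i in seq_along(classes)) {
    t <- ifelse(y == classes[i], 1, -1)
    b[i] <- mean(t)
    w[, i] <- solve(gram, crossprod(xs, t - b[i]))
  }
  structure(list(classes = classes, weights = w, intercepts = b,
                 center = mu, scale = sg,
                 features = colnames(x) %||% paste0("f", seq_len(d))),
            class = "linear_clf")
}

# Decision scores, samples x classes.
clf_scores <- function(fit, x) {
  xs <- sweep(sweep(as.matrix(x), 2, fit$center), 2, fit$scale, "/")
  sweep(xs %*% fit$weights, 2, fit$intercepts, "+")
}

#' @export
predict.linear_clf <- function(object, x, ...) {
  s <- clf_scores(object, x)
  object$classes[max.col(s, ties.method = "first")]
}

# Deterministic stratified fold ids: round-robin within each class in row
# order, so fitness is a pure function of (mask, table, folds).
stratified_fold_ids <- function(y, k) {
  ids <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    ids[idx] <- rep_len(seq_len(k), length(idx))
  }
  ids
}

#' Fitness specification for wrapper feature selection
#'
#' The wrapper objective is the stratified cross-validated error
#' `1 - accuracy` of the linear classifier restricted to the candidate
#' feature subset, evaluated strictly inside the training data handed to
#' the optimizer.
#'
#' @param cv_folds Stratified CV folds used inside the fitness. Default 3.
#' @param lambda Ridge penalty of the linear classifier.
#' @return A `fitness_spec` object.
#' @export
fitness_spec <- function(cv_folds = 3L, lambda = 1) {
  structure(list(cv_folds = as.integer(cv_folds), lambda = lambda),
            class = "fitness_spec")
}

#' Wrapper fitness: cross-validated error of a feature mask
#'
#' Returns `1 - accuracy` of the linear fitness classifier trained on the
#' masked features under deterministic stratified cross-validation. The
#' empty mask is maximally penalized with exactly 1.0.
#'
#' @param mask Binary (0/1 or logical) vector over the table's features.
#' @param table Labeled sample table.
#' @param spec A [fitness_spec()].
#' @return Error in `[0, 1]`.
#' @export
fitness_error <- function(mask, table, spec = fitness_spec()) {
  mask <- as.logical(mask)
  if (!any(mask)) return(1.0)
  y <- table$label
  if (length(unique(y)) < 2) abort("Fitness needs at least two classes.")
  x <- feature_matrix(table)[, mask, drop = FALSE]
  k <- min(spec$cv_folds, min(table(y)))
  if (k < 2) abort("Too few samples per class for cross-validation.")
  folds <- stratified_fold_ids(y, k)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_linear_clf(x[tr, , drop = FALSE], y[tr], lambda = spec$lambda)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  1 - correct / length(y)
}
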