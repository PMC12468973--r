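# Metrics and statistical utilities: per-class and macro classification
# metrics, fold-aggregated cross-validated reporting, the paired McNemar
# test, Brier scores and ROC/PR curves.

#' Classification metrics
#'
#' Standard precision, recall, F1 and accuracy. Binary mode reports the
#' positive class (label 1, the high-grade class); macro mode reports
#' unweighted means over classes.
#'
#' @param truth Integer vector of true labels.
#' @param estimate Integer vector of predicted labels.
#' @param averaging `"binary"` (positive class = 1) or `"macro"`.
#' @return A `metrics_report`: list with `metrics` (tibble), `per_class`
#'   (tibble) and `confusion` (matrix, rows = truth).
#' @export
classification_metrics <- function(truth, estimate,
                                   averaging = c("binary", "macro")) {
  averaging <- match.arg(averaging)
  stopifnot(length(truth) == length(estimate))
  classes <- sort(unique(c(truth, estimate)))
  cm <- table(factor(truth, levels = classes),
              factor(estimate, levels = classes))
  cm <- unclass(as.matrix(cm))
  per_class <- purrr::map_dfr(seq_along(classes), function(i) {
    tp <- cm[i, i]; fp <- sum(cm[, i]) - tp; fn <- sum(cm[i, ]) - tp
    tibble(class = classes[i],
           precision = if (tp + fp == 0) 0 else tp / (tp + fp),
           recall = if (tp + fn == 0) 0 else tp / (tp + fn),
           support = sum(cm[i, ])) |>
      mutate(f1 = ifelse(.data$precision + .data$recall == 0, 0,
                         2 * .data$precision * .data$recall /
                           (.data$precision + .data$recall)))
  })
  acc <- sum(diag(cm)) / sum(cm)
  metrics <- if (averaging == "binary") {
    pos <- per_class |> filter(.data$class == 1L)
    if (nrow(pos) == 0) abort("Binary averaging needs a positive class 1.")
    tibble(precision = pos$precision, recall = pos$recall, f1 = pos$f1,
           accuracy = acc)
  } else {
    tibble(precision = mean(per_class$precision),
           recall = mean(per_class$recall),
           f1 = mean(per_class$f1), accuracy = acc)
  }
  structure(list(metrics = metrics, per_class = per_class, confusion = cm,
                 averaging = averaging),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> (%s averaging)\n", x$averaging))
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cross-validated pipeline report
#'
#' For each group-atomic stratified fold: runs feature selection on the
#' fold-training data only (unless `select = FALSE`), trains a learner on
#' the selected features, scores the held-out fold, and aggregates
#' mean, standard deviation and normal-approximation 95% confidence
#' intervals across folds.
#'
#' @param table Labeled sample table.
#' @param agent An [agent_config()], or any function
#'   `f(train_table) -> function(test_table) -> predictions` standing in as
#'   the learner (e.g. a majority-class stub for testing).
#' @param k Number of folds. Default 5.
#' @param select Run per-fold ensemble + Shapley selection. Default FALSE
#'   (selection is expensive; enable for the full pipeline).
#' @param selection_config,selection_spec,theta Passed to
#'   [select_features()] when `select = TRUE`.
#' @param averaging Metric averaging mode.
#' @param seed Integer seed.
#' @return A `crossval_report`: list with `folds` (per-fold metric tibble),
#'   `summary` (mean, sd, and 95% CI per metric) and `masks` (per-fold
#'   selection masks or NULL).
#' @export
crossval_report <- function(table, agent = agent_config(), k = 5L,
                            select = FALSE,
                            selection_config = optimizer_config(),
                            selection_spec = fitness_spec(), theta = 0.9,
                            averaging = c("binary", "macro"), seed = 1L) {
  averaging <- match.arg(averaging)
  folds <- kfold_splits(table, k = k, seed = seed)
  masks <- vector("list", k)
  fold_rows <- list()
  for (f in seq_len(k)) {
    tr <- as_tibble(table)[folds[[f]]$train, , drop = FALSE]
    va <- as_tibble(table)[folds[[f]]$validation, , drop = FALSE]
    if (length(unique(va$label)) < 2) {
      warn(sprintf("Fold %d has a single class; skipped.", f))
      next
    }
    if (select) {
      rep_f <- select_features(tr, config = selection_config,
                               spec = selection_spec, theta = theta,
                               seed = derive_seed(seed, 1000L + f))
      keep <- c(intersect(RESERVED_COLUMNS, names(tr)),
                selected_features(rep_f$final))
      tr <- as_tibble(tr)[, keep, drop = FALSE]
      va <- as_tibble(va)[, keep, drop = FALSE]
      masks[[f]] <- rep_f$final
    }
    norm <- zscore_normalize(tr)
    va_n <- zscore_normalize(va, stats = norm$stats)$table
    if (is.function(agent)) {
      predictor <- agent(norm$table)
      preds <- predictor(va_n)
    } else {
      cfg <- agent
      cfg$seed <- derive_seed(seed, 2000L + f)
      pol <- train_agent(norm$table, cfg)
      preds <- predict(pol, va_n)
    }
    m <- classification_metrics(va$label, preds, averaging = averaging)
    fold_rows[[f]] <- mutate(m$metrics, fold = f)
  }
  folds_tbl <- bind_rows(fold_rows)
  if (nrow(folds_tbl) == 0) abort("All folds were degenerate.")
  kk <- nrow(folds_tbl)
  summary <- folds_tbl |>
    tidyr::pivot_longer(c("precision", "recall", "f1", "accuracy"),
                        names_to = "metric") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value),
              sd = if (n() > 1) sd(.data$value) else 0, .groups = "drop") |>
    mutate(ci_lo = .data$mean - qnorm(0.975) * .data$sd / sqrt(kk),
           ci_hi = .data$mean + qnorm(0.975) * .data$sd / sqrt(kk))
  structure(list(folds = folds_tbl, summary = summary, masks = masks, k = k),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %d folds\n", x$k))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Paired McNemar test between two classifiers
#'
#' Continuity-corrected statistic `(|b - c| - 1)^2 / (b + c)` on the
#' discordant counts of two prediction vectors against shared ground truth;
#' when `b + c < 25` the p-value is the exact two-sided binomial tail
#' instead of the chi-square approximation.
#'
#' @param truth True labels.
#' @param pred_a,pred_b Predictions of the two classifiers.
#' @return List with `statistic`, `p_value`, and discordant counts `b`
#'   (A right, B wrong) and `c` (A wrong, B right).
#' @export
mcnemar_paired <- function(truth, pred_a, pred_b) {
  stopifnot(length(truth) == length(pred_a), length(truth) == length(pred_b))
  right_a <- pred_a == truth
  right_b <- pred_b == truth
  b <- sum(right_a & !right_b)
  c_ <- sum(!right_a & right_b)
  if (b + c_ == 0) {
    return(list(statistic = 0, p_value = 1, b = b, c = c_))
  }
  stat <- (abs(b - c_) - 1)^2 / (b + c_)
  p <- if (b + c_ < 25) {
    min(1, 2 * pbinom(min(b, c_), b + c_, 0.5))
  } else {
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, b = b, c = c_)
}

#' Brier score of probabilistic predictions
#'
#' Binary mode: mean squared difference between the positive-class
#' probability and the 0/1 outcome. Multiclass: mean over samples of the
#' squared distance between the probability vector and the one-hot truth.
#'
#' @param prob Probability matrix (samples x classes, columns ordered by
#'   class 0, 1, ...) or a vector of positive-class probabilities.
#' @param truth Integer true labels.
#' @return Scalar Brier score.
#' @export
brier_score <- function(prob, truth) {
  if (is.matrix(prob) && ncol(prob) == 2) prob <- prob[, 2]
  if (!is.matrix(prob)) {
    mean((prob - as.numeric(truth == 1))^2)
  } else {
    onehot <- matrix(0, nrow(prob), ncol(prob))
    onehot[cbind(seq_len(nrow(prob)), truth + 1L)] <- 1
    mean(rowSums((prob - onehot)^2))
  }
}

#' ROC and precision-recall curves with trapezoidal areas
#'
#' Threshold sweep over positive-class scores against binary labels.
#'
#' @param scores Numeric scores for the positive class (label 1), e.g. the
#'   softmax probability from [predict_proba()].
#' @param labels Binary 0/1 labels.
#' @return List with `roc` (tibble: threshold, fpr, tpr), `pr` (tibble:
#'   threshold, recall, precision), `auc_roc`, `auc_pr`.
#' @export
roc_pr_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) abort("Both classes must be present.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(which(diff(s) != 0), length(s))   # one point per threshold
  tpr <- c(0, tp[keep] / pos); fpr <- c(0, fp[keep] / neg)
  prec <- c(1, tp[keep] / (tp[keep] + fp[keep]))
  rec <- c(0, tp[keep] / pos)
  trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(
    roc = tibble(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr),
    pr = tibble(threshold = c(Inf, s[keep]), recall = rec, precision = prec),
    auc_roc = trapezoid(fpr, tpr),
    auc_pr = trapezoid(rec, prec)
  )
}
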