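# Majority-vote ensembling of the three optimizer masks and Shapley-value
# cumulative-threshold refinement. For the linear fitness classifier the
# Shapley values are exact and closed-form: phi_ij = w_j (x_ij - mean_j).

#' Construct a selection mask
#'
#' @param mask Integer/logical 0/1 vector.
#' @param namespace Character vector of feature names, same length.
#' @param provenance One of `"hho"`, `"mgto"`, `"zoa"`, `"ensemble"`,
#'   `"shap"`, `"manual"`.
#' @param votes Optional integer per-feature vote counts (ensemble masks).
#' @return A `selection_mask` object.
#' @export
selection_mask <- function(mask, namespace,
                           provenance = c("manual", "hho", "mgto", "zoa",
                                          "ensemble", "shap"),
                           votes = NULL) {
  provenance <- match.arg(provenance)
  mask <- as.integer(as.logical(mask))
  if (length(mask) != length(namespace)) {
    abort("Mask and namespace lengths differ.")
  }
  structure(list(mask = mask, namespace = namespace,
                 provenance = provenance, votes = votes),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask> %s: %d of %d features\n",
              x$provenance, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Features selected by a mask
#'
#' @param x A `selection_mask`.
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(x) x$namespace[x$mask == 1L]

#' Majority-vote ensemble of selection masks
#'
#' A feature enters the ensemble mask iff at least `min_votes` of the input
#' masks selected it (default 2 of 3). Per-feature vote counts are kept on
#' the result.
#'
#' @param masks List of [selection_mask()]s over an identical namespace.
#' @param min_votes Minimum votes for retention. Default 2.
#' @return A `selection_mask` with provenance `"ensemble"`.
#' @export
majority_vote <- function(masks, min_votes = 2L) {
  stopifnot(length(masks) >= 1)
  ns <- masks[[1]]$namespace
  for (m in masks[-1]) {
    if (!identical(m$namespace, ns)) {
      abort("Masks have mismatched namespaces.", class = "radqn_schema_error")
    }
  }
  votes <- Reduce(`+`, map(masks, "mask"))
  selection_mask(votes >= min_votes, ns, provenance = "ensemble", votes = votes)
}

#' Exact Shapley importances of a linear classifier
#'
#' For a linear model the Shapley value of feature `j` for sample `i` is
#' `phi_ij = w_j (x_ij - mean_j)` (independent-feature closed form, with the
#' background mean taken over the supplied table); the per-feature
#' importance is `mean_i |phi_ij|`. For more than two classes the
#' importance is averaged over the one-vs-rest weight vectors.
#'
#' @param fit A fitted [fit_linear_clf()] model on the masked features.
#' @param table Sample table providing the explanation set.
#' @param mask A [selection_mask()] restricting to the model's features.
#' @return An `importance_vector`: tibble with `feature`, `importance` and
#'   descending-importance `rank` (ties broken by feature order).
#' @export
shap_importances <- function(fit, table, mask) {
  if (!inherits(fit, "linear_clf")) abort("`fit` must be a fitted linear_clf.")
  feats <- selected_features(mask)
  x <- feature_matrix(table)[, feats, drop = FALSE]
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  centered <- sweep(xs, 2, colMeans(xs))
  # |phi| per class weight vector, averaged over classes (binary: the two
  # one-vs-rest weight vectors are sign-opposites, so this equals either one)
  per_class <- vapply(seq_len(ncol(fit$weights)), function(k) {
    colMeans(abs(sweep(centered, 2, fit$weights[, k], "*")))
  }, numeric(length(feats)))
  imp <- rowMeans(matrix(per_class, nrow = length(feats)))
  ranking <- order(-imp, seq_along(imp))
  out <- tibble(feature = feats, importance = as.numeric(imp),
                rank = match(seq_along(imp), ranking))
  class(out) <- c("importance_vector", class(out))
  out
}

#' Cumulative-share Shapley selection
#'
#' Takes features in descending importance until their cumulative share of
#' total importance first reaches `theta`, inclusive of the crossing
#' feature. Ties in importance are broken by original feature order.
#'
#' @param importances An `importance_vector` from [shap_importances()].
#' @param theta Cumulative-share threshold in (0, 1]. Default 0.9.
#' @param namespace Optional full namespace the returned mask should span;
#'   defaults to the importance features themselves.
#' @return A `selection_mask` with provenance `"shap"`.
#' @export
cumulative_select <- function(importances, theta = 0.9, namespace = NULL) {
  stopifnot(theta > 0, theta <= 1)
  total <- sum(importances$importance)
  if (total <= 0) {
    abort("All importances are zero; no ranking possible.",
          class = "radqn_degenerate_error")
  }
  ord <- order(importances$rank)
  shares <- cumsum(importances$importance[ord]) / total
  n_keep <- which(shares >= theta - 1e-12)[1]
  keep_feats <- importances$feature[ord][seq_len(n_keep)]
  ns <- namespace %||% importances$feature
  selection_mask(ns %in% keep_feats, ns, provenance = "shap")
}

#' End-to-end ensemble feature selection with Shapley refinement
#'
#' Runs the three metaheuristics on the (training) table, majority-votes
#' their best masks, fits the linear classifier on the ensemble features,
#' computes exact linear Shapley importances and keeps the top features
#' reaching `theta` cumulative importance. Must be called on training data
#' only; in cross-validation, call it inside each fold.
#'
#' @param table Labeled training sample table.
#' @param config An [optimizer_config()].
#' @param spec A [fitness_spec()].
#' @param theta Cumulative Shapley share to retain. Default 0.9.
#' @param min_votes Ensemble vote threshold. Default 2.
#' @param seed Integer seed (per-optimizer sub-seeds are derived from it).
#' @return A `selection_report`: list with `final` (shap-refined
#'   [selection_mask()]), `ensemble`, `algorithm_masks`, `traces`,
#'   `importances`, and the configuration used.
#' @export
select_features <- function(table, config = optimizer_config(),
                            spec = fitness_spec(), theta = 0.9,
                            min_votes = 2L, seed = 1L) {
  validate_feature_table(table)
  ns <- feature_names(table)
  d <- length(ns)
  fitness <- function(mask) fitness_error(mask, table, spec)
  algs <- c("hho", "mgto", "zoa")
  results <- imap(setNames(algs, algs), function(a, nm) {
    run_optimizer(a, config, fitness, d,
                  seed = derive_seed(seed, match(a, algs)))
  })
  alg_masks <- imap(results, function(r, a) {
    selection_mask(r$best$mask, ns, provenance = a)
  })
  ensemble <- majority_vote(unname(alg_masks), min_votes = min_votes)
  if (sum(ensemble$mask) == 0) {
    warn("Empty ensemble mask; falling back to the union of algorithm masks.")
    ensemble <- majority_vote(unname(alg_masks), min_votes = 1L)
  }
  x <- feature_matrix(table)[, selected_features(ensemble), drop = FALSE]
  fit <- fit_linear_clf(x, table$label, lambda = spec$lambda)
  importances <- shap_importances(fit, table, ensemble)
  final <- cumulative_select(importances, theta = theta, namespace = ns)
  structure(list(final = final, ensemble = ensemble,
                 algorithm_masks = alg_masks,
                 traces = map(results, "trace"),
                 importances = importances,
                 config = config, fitness_spec = spec, theta = theta,
                 seed = seed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  for (a in names(x$algorithm_masks)) {
    cat(sprintf("  %-8s %3d features (fitness %.4f)\n", a,
                sum(x$algorithm_masks[[a]]$mask), min(x$traces[[a]])))
  }
  cat(sprintf("  ensemble %3d features (votes >= 2)\n", sum(x$ensemble$mask)))
  cat(sprintf("  shap     %3d features (theta = %.2f)\n", sum(x$final$mask), x$theta))
  invisible(x)
}

#' Serialize a selection report to JSON
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  out <- list(
    namespace = report$final$namespace,
    algorithm_masks = map(report$algorithm_masks, "mask"),
    votes = report$ensemble$votes,
    ensemble_mask = report$ensemble$mask,
    importances = report$importances,
    final_mask = report$final$mask,
    theta = report$theta,
    config = unclass(report$config),
    seed = report$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
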