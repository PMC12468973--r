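# Grouped, stratified data splitting.
#
# Augmented copies of a patient share that patient's group_id; any split that
# put copies of one patient on both sides would leak test information into
# training. Both splitters below are therefore group-atomic: a group_id is
# assigned wholly to one partition.

# Per-class train counts by largest remainder, so the total equals
# floor(fraction * n) exactly when fraction * n is integral.
class_train_targets <- function(labels, fraction) {
  counts <- table(labels)
  exact <- as.numeric(counts) * fraction
  base <- floor(exact)
  total_target <- floor(fraction * length(labels) + 1e-9)
  deficit <- total_target - sum(base)
  if (deficit > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(deficit)]] <- base[order_rem[seq_len(deficit)]] + 1
  }
  setNames(as.integer(base), names(counts))
}

#' Grouped stratified train/test split
#'
#' Splits a labeled sample table into train and test partitions such that no
#' `group_id` (origin patient, shared by its augmented copies) appears on
#' both sides, and class proportions are preserved as closely as group
#' atomicity allows. With singleton groups the train size is exactly
#' `floor(fraction * n)` per-class by largest remainder, which reproduces
#' 595 -> 476/119 and 705 -> 564/141 at `fraction = 0.8`.
#'
#' @param table Labeled sample table.
#' @param fraction Train fraction in (0, 1). Default 0.8.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return Named list with tibbles `train` and `test`.
#' @export
split_grouped <- function(table, fraction = 0.8, seed = 1L) {
  validate_feature_table(table)
  if (!("label" %in% names(table)) || anyNA(table$label)) {
    abort("`split_grouped()` needs complete labels.")
  }
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")

  groups <- as_tibble(table) |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$group_id) |>
    summarise(label = .data$label[1], size = n(),
              rows = list(.data$.row), .groups = "drop")
  if (any(groups$size > fraction * nrow(table))) {
    warn("A single group exceeds the train fraction; stratification is approximate.")
  }
  targets <- class_train_targets(table$label, fraction)

  rng <- local_seed(seed)
  train_rows <- integer(0)
  for (cl in names(targets)) {
    g <- groups |> filter(.data$label == as.integer(cl))
    g <- g[sample.int(nrow(g)), , drop = FALSE]
    need <- targets[[cl]]
    got <- 0L
    for (i in seq_len(nrow(g))) {
      if (got >= need) break
      # greedy fill; overshoot only if the group is closer to target than not
      if (got + g$size[i] <= need || (need - got) > g$size[i] / 2) {
        train_rows <- c(train_rows, g$rows[[i]])
        got <- got + g$size[i]
      }
    }
  }
  train_rows <- sort(train_rows)
  list(train = as_tibble(table)[train_rows, , drop = FALSE],
       test = as_tibble(table)[-train_rows, , drop = FALSE])
}

#' Group-atomic stratified k-fold assignment
#'
#' Partitions the rows of a labeled table into `k` cross-validation folds.
#' Groups are dealt whole, round-robin within each class after a seeded
#' shuffle, so folds are group-atomic and class-stratified, and the
#' validation folds partition the samples exactly.
#'
#' @param table Labeled sample table.
#' @param k Number of folds (>= 2). Default 5.
#' @param seed Integer seed.
#' @return List of `k` elements, each a list with integer row indices
#'   `train` and `validation`.
#' @export
kfold_splits <- function(table, k = 5L, seed = 1L) {
  validate_feature_table(table)
  if (k < 2) abort("`k` must be at least 2.")
  if (!("label" %in% names(table)) || anyNA(table$label)) {
    abort("`kfold_splits()` needs complete labels.")
  }
  groups <- as_tibble(table) |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$group_id) |>
    summarise(label = .data$label[1], rows = list(.data$.row), .groups = "drop")
  if (k > nrow(groups)) {
    abort("`k` exceeds the number of groups.", class = "radqn_config_error")
  }
  rng <- local_seed(seed)
  fold_of_group <- integer(nrow(groups))
  for (cl in unique(groups$label)) {
    idx <- which(groups$label == cl)
    idx <- idx[sample.int(length(idx))]
    fold_of_group[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    val <- sort(unlist(groups$rows[fold_of_group == f]))
    list(train = setdiff(seq_len(nrow(table)), val), validation = val)
  })
}

#' Z-score normalization of feature columns
#'
#' In fit mode (`stats = NULL`) computes per-feature mean and standard
#' deviation from `table` and standardizes; features with zero spread map
#' to 0. In transform mode applies previously fitted statistics, e.g.
#' train-set statistics to held-out samples.
#'
#' @param table Sample table.
#' @param stats Optional statistics tibble (columns `feature`, `mean`, `sd`)
#'   returned by a previous fit-mode call.
#' @return List with `table` (normalized) and `stats`.
#' @export
zscore_normalize <- function(table, stats = NULL) {
  validate_feature_table(table)
  fn <- feature_names(table)
  if (is.null(stats)) {
    stats <- tibble(
      feature = fn,
      mean = map_dbl(fn, ~ mean(table[[.x]])),
      sd = map_dbl(fn, ~ sd(table[[.x]]))
    )
  } else {
    if (!setequal(stats$feature, fn) || !identical(sort(stats$feature), sort(fn))) {
      abort("Feature namespace of `stats` does not match `table`.",
            class = "radqn_schema_error")
    }
    stats <- stats[match(fn, stats$feature), , drop = FALSE]
  }
  out <- as_tibble(table)
  for (i in seq_along(fn)) {
    s <- stats$sd[i]
    out[[fn[i]]] <- if (is.na(s) || s == 0) rep(0, nrow(out)) else
      (out[[fn[i]]] - stats$mean[i]) / s
  }
  list(table = out, stats = stats)
}

#' Fuse modality-specific feature tables
#'
#' Concatenates the selected features of per-modality tables for the same
#' samples into one composite table, prefixing each feature with its
#' modality (`"<modality>.<feature>"`) to keep provenance. Tables must be
#' aligned on `sample_id`.
#'
#' @param tables List of sample tables, one per modality.
#' @param masks Optional list of [selection_mask()]s (or plain logical or
#'   0/1 vectors over each table's namespace), one per table; `NULL` keeps
#'   all features.
#' @return A fused sample table; the `modality` column is the `+`-joined
#'   composite tag.
#' @export
fuse_modalities <- function(tables, masks = NULL) {
  stopifnot(length(tables) >= 1)
  if (!is.null(masks) && length(masks) != length(tables)) {
    abort("Need one mask per table.")
  }
  ids <- tables[[1]]$sample_id
  for (t in tables[-1]) {
    if (!identical(t$sample_id, ids)) {
      abort("Tables are not aligned on sample_id.", class = "radqn_alignment_error")
    }
  }
  meta_cols <- intersect(RESERVED_COLUMNS, names(tables[[1]]))
  out <- as_tibble(tables[[1]])[, setdiff(meta_cols, "modality"), drop = FALSE]
  tags <- character(length(tables))
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    fn <- feature_names(tab)
    keep <- if (is.null(masks)) rep(TRUE, length(fn)) else {
      m <- masks[[i]]
      if (inherits(m, "selection_mask")) as.logical(m$mask) else as.logical(m)
    }
    if (length(keep) != length(fn)) abort("Mask length does not match namespace.")
    tag <- if ("modality" %in% names(tab)) as.character(tab$modality[1]) else paste0("m", i)
    tags[i] <- tag
    sel <- fn[keep]
    if (length(sel) > 0) {
      block <- as_tibble(tab)[, sel, drop = FALSE]
      names(block) <- paste(tag, sel, sep = ".")
      out <- bind_cols(out, block)
    }
  }
  out$modality <- paste(tags, collapse = "+")
  relocate(out, "modality", .after = "group_id")
}
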