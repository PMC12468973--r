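# Synthetic radiomics-like tables with planted class signal. The generator
# reproduces the *structure* of the motivating cohort — class imbalance
# (76 low-grade vs 293 high-grade), 105-feature namespace, survival classes
# of 75/86/74 cases over 0-1800 days, and the augmentation multiplicities
# that take 76 -> 304 and 235 -> 705 — not the marginal distributions of
# real texture features.

#' Specification of a synthetic radiomics cohort
#'
#' @param n_per_class Integer vector of per-class sample counts. Defaults to
#'   the motivating cohort's grading imbalance `c(76, 293)`.
#' @param n_features Total number of features. Default 105, the size of the
#'   packaged manifest.
#' @param n_informative Number of class-informative features. Default 10.
#' @param effect_size Standardized mean shift of informative features
#'   between adjacent classes. Default 1.5.
#' @param noise_sd Standard deviation of the feature noise. Default 1.
#' @param day_ranges List of `(low, high)` survival-day bands per class,
#'   used by [generate_survival_table()]. Defaults to the three survival
#'   class bands `(0,250), (251,500), (501,1800)`.
#' @param age_mean,age_sd Normal age distribution (years). Defaults 60, 12.
#' @param seed Integer seed.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_per_class = c(76L, 293L), n_features = 105L,
                       n_informative = 10L, effect_size = 1.5, noise_sd = 1,
                       day_ranges = list(c(0L, 250L), c(251L, 500L), c(501L, 1800L)),
                       age_mean = 60, age_sd = 12, seed = 1L) {
  stopifnot(n_informative <= n_features, all(n_per_class > 0), n_features > 0)
  for (r in day_ranges) {
    if (r[2] > 1800 || r[1] < 0) abort("Day ranges must lie within [0, 1800].")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 day_ranges = day_ranges, age_mean = age_mean, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

synth_feature_names <- function(n_features) {
  man <- manifest_features(read_manifest())
  if (n_features <= length(man)) man[seq_len(n_features)]
  else c(man, paste0("synth_Feature", seq_len(n_features - length(man))))
}

#' Generate a synthetic grading (classification) table
#'
#' Draws Gaussian feature noise and plants a class-dependent mean shift of
#' `effect_size` standard deviations on `n_informative` randomly chosen
#' features. Samples get singleton groups (one patient per row); labels are
#' `0 .. length(n_per_class) - 1`.
#'
#' @param spec A [synth_spec()].
#' @param modality Modality tag for the table. Default `"FLAIR"`.
#' @return List with `table` (sample table tibble) and `informative`
#'   (integer indices of the planted features in the namespace).
#' @export
generate_classification_table <- function(spec = synth_spec(), modality = "FLAIR") {
  local_seed(spec$seed)
  n <- sum(spec$n_per_class)
  d <- spec$n_features
  labels <- rep(seq_along(spec$n_per_class) - 1L, spec$n_per_class)
  informative <- sort(sample.int(d, spec$n_informative))
  x <- matrix(rnorm(n * d, sd = spec$noise_sd), n, d)
  # class-ordered shifts: monotone across classes so multiclass macro
  # metrics respond to the planted signal
  if (spec$n_informative > 0) {
    x[, informative] <- x[, informative] +
      matrix(labels * spec$effect_size * spec$noise_sd, n, spec$n_informative)
  }
  colnames(x) <- synth_feature_names(d)
  tab <- bind_cols(
    tibble(sample_id = sprintf("s%04d", seq_len(n)),
           group_id = sprintf("g%04d", seq_len(n)),
           modality = modality, label = labels),
    as_tibble(x)
  )
  list(table = validate_feature_table(tab), informative = informative)
}

#' Generate a synthetic survival table
#'
#' Three-class survival cohort: per-class counts default to 75/86/74 (a
#' 235-row table); survival days are uniform within each class band and the
#' label is re-derived through [bin_survival_days()], so labels and days are
#' consistent by construction. An `age` column is drawn from the spec's
#' normal distribution.
#'
#' @param spec A [synth_spec()]; `n_per_class` should have one entry per
#'   survival class. Default `c(75, 86, 74)`.
#' @param modality Modality tag.
#' @return List with `table` and `informative` as in
#'   [generate_classification_table()].
#' @export
generate_survival_table <- function(spec = NULL, modality = "FLAIR") {
  spec <- spec %||% synth_spec(n_per_class = c(75L, 86L, 74L))
  if (length(spec$n_per_class) != length(spec$day_ranges)) {
    abort("Need one day range per survival class.")
  }
  out <- generate_classification_table(spec, modality = modality)
  tab <- out$table
  local_seed(derive_seed(spec$seed, 211L))
  days <- integer(nrow(tab))
  for (k in seq_along(spec$day_ranges)) {
    idx <- which(tab$label == k - 1L)
    r <- spec$day_ranges[[k]]
    days[idx] <- sample(seq.int(r[1], r[2]), length(idx), replace = TRUE)
  }
  tab$survival_days <- days
  tab$age <- round(rnorm(nrow(tab), spec$age_mean, spec$age_sd), 1)
  tab$label <- bin_survival_days(tab$survival_days)
  out$table <- relocate(tab, "survival_days", "age", .after = "label")
  out
}

#' Label-preserving feature-space augmentation
#'
#' Emulates image-space augmentation (flips, rotations, noise injection) at
#' the feature-table level: each original row gains `copies` jittered
#' duplicates that keep its label, survival days and `group_id`, so grouped
#' splitting keeps a patient's copies together. With `copies = 3` a 76-row
#' class grows to 304 rows; with `copies = 2` a 75/86/74 survival cohort
#' grows to 225/258/222 (705 rows).
#'
#' @param table Sample table.
#' @param copies Nonnegative number of jittered copies per original row.
#' @param jitter_sd Jitter standard deviation as a fraction of each
#'   feature's empirical sd. Default 0.1.
#' @param seed Integer seed.
#' @param classes Optional label subset to augment (e.g. only the minority
#'   class); `NULL` augments all rows.
#' @return Augmented sample table; originals first, in input order.
#' @export
augment_table <- function(table, copies, jitter_sd = 0.1, seed = 1L,
                          classes = NULL) {
  validate_feature_table(table)
  if (copies < 0) abort("`copies` must be nonnegative.")
  copies <- as.integer(copies)
  if (copies == 0L) return(as_tibble(table))
  local_seed(seed)
  fn <- feature_names(table)
  sds <- map_dbl(fn, ~ sd(table[[.x]]))
  sds[is.na(sds) | sds == 0] <- 0
  rows <- if (is.null(classes)) seq_len(nrow(table)) else
    which(table$label %in% classes)
  out <- as_tibble(table)
  blocks <- vector("list", copies)
  for (cp in seq_len(copies)) {
    block <- as_tibble(table)[rows, , drop = FALSE]
    block$sample_id <- paste0(block$sample_id, "_aug", cp)
    for (i in seq_along(fn)) {
      block[[fn[i]]] <- block[[fn[i]]] +
        rnorm(length(rows), sd = jitter_sd * sds[i])
    }
    blocks[[cp]] <- block
  }
  bind_rows(out, blocks)
}
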