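#' @importFrom rlang .data %||% abort warn
#' @importFrom dplyr mutate select filter arrange group_by ungroup summarise
#'   bind_rows bind_cols across all_of left_join n pull relocate count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_int map_dbl map_chr map_lgl imap walk
#' @importFrom stats sd rnorm runif setNames predict qnorm pbinom pchisq
#'   rbinom quantile
#' @importFrom utils head tail
NULL

# Reserved (non-feature) columns of a sample table, in canonical order.
RESERVED_COLUMNS <- c("sample_id", "group_id", "modality", "label",
                      "survival_days", "age")

#' Feature columns of a sample table
#'
#' A sample table is an ordinary tibble with the reserved metadata columns
#' `sample_id`, `group_id`, `modality`, `label`, `survival_days`, `age`
#' (the last three optional) followed by one numeric column per radiomics
#' feature. Every function in the package treats the non-reserved columns,
#' in their current order, as the feature namespace.
#'
#' @param table A sample table (data frame).
#' @return Character vector of feature column names, in table order.
#' @export
#' @examples
#' tab <- tibble::tibble(sample_id = "s1", group_id = "g1",
#'                       modality = "FLAIR", label = 1L, f1 = 0.2, f2 = 1.1)
#' feature_names(tab)
feature_names <- function(table) {
  setdiff(names(table), RESERVED_COLUMNS)
}

#' Feature matrix of a sample table
#'
#' @param table A sample table.
#' @return Numeric matrix, samples x features, with feature column names.
#' @export
feature_matrix <- function(table) {
  fn <- feature_names(table)
  m <- as.matrix(as_tibble(table)[, fn, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Validate a sample table
#'
#' Checks the structural invariants every pipeline stage relies on: a
#' `sample_id` and `group_id` column, unique feature names, numeric and
#' finite feature columns, and labels in the admissible set when present
#' (0/1 for grading tables, 0/1/2 for survival tables).
#'
#' @param table A sample table.
#' @param task Either `"any"` (default), `"grading"` (labels must be 0/1) or
#'   `"survival"` (labels must be 0/1/2).
#' @return The table, invisibly, on success; otherwise an error.
#' @export
validate_feature_table <- function(table, task = c("any", "grading", "survival")) {
  task <- match.arg(task)
  if (!is.data.frame(table)) abort("`table` must be a data frame.")
  missing_cols <- setdiff(c("sample_id", "group_id"), names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")), class = "radqn_schema_error")
  }
  if (anyDuplicated(names(table))) {
    abort(paste0("Duplicated column name(s): ",
                 paste(unique(names(table)[duplicated(names(table))]), collapse = ", ")),
          class = "radqn_schema_error")
  }
  fn <- feature_names(table)
  for (f in fn) {
    if (!is.numeric(table[[f]])) {
      abort(paste0("Feature column '", f, "' is not numeric."),
            class = "radqn_parse_error")
    }
  }
  if ("label" %in% names(table) && any(!is.na(table$label))) {
    lv <- table$label[!is.na(table$label)]
    admissible <- switch(task, any = 0:2, grading = 0:1, survival = 0:2)
    if (!all(lv %in% admissible)) {
      abort(paste0("Labels outside admissible set {",
                   paste(admissible, collapse = ","), "}."),
            class = "radqn_schema_error")
    }
  }
  invisible(table)
}

#' Read a radiomics feature table from delimited text
#'
#' Expects a header row; the reserved columns `sample_id`, `group_id`,
#' `modality`, `label`, `survival_days`, `age` are recognised by name
#' (only the first two are mandatory) and every remaining column is parsed
#' as a numeric feature. Non-numeric feature cells are reported with their
#' row and column coordinates.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return A validated sample table tibble; row order preserved.
#' @export
read_feature_table <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE,
                           name_repair = "minimal")
  missing_cols <- setdiff(c("sample_id", "group_id"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("File '", path, "' lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")), class = "radqn_schema_error")
  }
  if (anyDuplicated(names(raw))) {
    abort(paste0("File '", path, "' has duplicated column name(s): ",
                 paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", ")),
          class = "radqn_schema_error")
  }
  tab <- raw
  int_cols <- intersect(c("label", "survival_days"), names(tab))
  for (col in int_cols) tab[[col]] <- as.integer(tab[[col]])
  if ("age" %in% names(tab)) tab[["age"]] <- as.numeric(tab[["age"]])
  for (f in feature_names(tab)) {
    parsed <- suppressWarnings(as.numeric(tab[[f]]))
    bad <- which(is.na(parsed) & !is.na(tab[[f]]) & tab[[f]] != "NA")
    if (length(bad) > 0) {
      abort(paste0("Non-numeric value '", tab[[f]][bad[1]], "' in feature column '",
                   f, "', row ", bad[1], "."), class = "radqn_parse_error")
    }
    tab[[f]] <- parsed
  }
  validate_feature_table(tab)
  tab
}

#' Write a sample table to delimited text
#'
#' Lossless inverse of [read_feature_table()]: full-precision numeric
#' formatting so that a write/read round trip reproduces feature values
#' exactly.
#'
#' @param table A sample table.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delim = ",") {
  validate_feature_table(table)
  out <- as_tibble(table)
  for (f in feature_names(out)) {
    out[[f]] <- sprintf("%.17g", out[[f]])
  }
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Survival class boundaries
#'
#' Day boundaries of the three overall-survival classes: short, medium and
#' long. Each edge is an inclusive upper bound, so with the defaults a
#' survival of exactly 250 days is short (class 0) and 251 days is medium
#' (class 1).
#'
#' @param edges Strictly increasing integer vector of three inclusive upper
#'   bounds, in days. Default `c(250, 500, 1800)`.
#' @return An object of class `survival_class_spec`.
#' @export
survival_class_spec <- function(edges = c(250L, 500L, 1800L)) {
  edges <- as.integer(edges)
  if (length(edges) != 3 || any(diff(edges) <= 0)) {
    abort("`edges` must be three strictly increasing day boundaries.")
  }
  structure(list(edges = edges), class = "survival_class_spec")
}

#' Bin survival days into survival classes
#'
#' Maps nonnegative survival durations to the discrete classes
#' 0 (short), 1 (medium), 2 (long) using inclusive upper bounds.
#'
#' @param days Vector of nonnegative integer survival durations.
#' @param spec A [survival_class_spec()].
#' @return Integer class vector (0, 1 or 2) of the same length as `days`.
#' @export
#' @examples
#' bin_survival_days(c(0, 250, 251, 500, 501, 1800))
bin_survival_days <- function(days, spec = survival_class_spec()) {
  if (any(days < 0, na.rm = TRUE)) abort("Negative survival days.")
  if (any(days > spec$edges[3], na.rm = TRUE)) {
    abort(paste0("Survival days above the last class boundary (",
                 spec$edges[3], ")."), class = "radqn_range_error")
  }
  as.integer(findInterval(days, spec$edges + 1L))
}

#' The packaged radiomics feature manifest
#'
#' Seven feature categories with the canonical category sizes of a 3D
#' radiomics extraction restricted to the original image: 14 shape, 18
#' first-order, 24 GLCM, 13 GLDM, 16 GLRLM, 15 GLSZM and 5 NGTDM features,
#' 105 in total. Feature names follow PyRadiomics conventions.
#'
#' @param path Optional path to a YAML manifest (`categories:` mapping
#'   category name to a list of feature names, plus a `version:` tag).
#'   Defaults to the manifest shipped with the package.
#' @return A `feature_manifest` object: list with `categories` (named list
#'   of character vectors) and `version`.
#' @export
read_manifest <- function(path = NULL) {
  path <- path %||% system.file("extdata", "feature_manifest.yaml", package = "radqn")
  doc <- yaml::read_yaml(path)
  man <- structure(list(categories = lapply(doc$categories, unlist),
                        version = doc$version %||% "unversioned"),
                   class = "feature_manifest")
  all_names <- unlist(man$categories, use.names = FALSE)
  if (anyDuplicated(all_names)) {
    abort("Manifest has duplicated feature names across categories.",
          class = "radqn_schema_error")
  }
  man
}

#' @export
print.feature_manifest <- function(x, ...) {
  cat("<feature_manifest> version", x$version, "\n")
  for (nm in names(x$categories)) {
    cat(sprintf("  %-12s %3d features\n", nm, length(x$categories[[nm]])))
  }
  cat("  total       ", sprintf("%3d", length(manifest_features(x))), "features\n")
  invisible(x)
}

#' Flat feature namespace of a manifest
#'
#' @param manifest A `feature_manifest`.
#' @return Character vector of all feature names, category order preserved.
#' @export
manifest_features <- function(manifest) {
  unlist(manifest$categories, use.names = FALSE)
}
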