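# Small fixtures built in code.

toy_table <- function(n = 6, d = 2, labels = rep(0:1, length.out = n),
                      groups = NULL, modality = "FLAIR", seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    colnames(x) <- paste0("feat", seq_len(d))
    tibble::as_tibble(x) |>
      dplyr::mutate(sample_id = sprintf("s%02d", seq_len(n)),
                    group_id = groups %||% sprintf("g%02d", seq_len(n)),
                    modality = modality, label = as.integer(labels),
                    .before = 1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A strongly separable two-class table for learning tests.
separable_table <- function(n_per_class = 30, d = 20, seed = 7) {
  g <- generate_classification_table(
    synth_spec(n_per_class = c(n_per_class, n_per_class), n_features = d,
               n_informative = 5, effect_size = 3, seed = seed))
  list(table = zscore_normalize(g$table)$table, informative = g$informative)
}

# A tiny fitted network of each variant over fixed dims.
tiny_net <- function(variant, d = 4, n_actions = 2, seed = 1) {
  qnet_init(d, n_actions, variant = variant, hidden = c(8L, 8L), seed = seed)
}
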