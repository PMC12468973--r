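test_that("feature table IO round-trips losslessly and reports schema errors", {
  tab <- toy_table(n = 3, d = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(feature_names(back), c("feat1", "feat2"))
  expect_identical(back$feat1, tab$feat1)   # full precision
  expect_identical(back$feat2, tab$feat2)
  expect_equal(back$label, tab$label)

  # missing mandatory column
  bad <- dplyr::select(tab, -"group_id")
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, p2)
  expect_error(read_feature_table(p2), class = "radqn_schema_error")

  # duplicated feature column
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group_id,feat1,feat1", "s1,g1,1.0,2.0"), p3)
  expect_error(read_feature_table(p3), class = "radqn_schema_error")

  # non-numeric feature cell reported with coordinates
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group_id,feat1", "s1,g1,1.0", "s2,g2,oops"), p4)
  err <- expect_error(read_feature_table(p4), class = "radqn_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "feat1")

  # empty table -> header-only file
  p5 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab[0, ], p5)
  expect_length(readLines(p5), 1)
})

test_that("packaged manifest has the seven radiomics categories and 105 features", {
  man <- read_manifest()
  counts <- vapply(man$categories, length, integer(1))
  expect_equal(unname(counts), c(14L, 18L, 24L, 13L, 16L, 15L, 5L))
  feats <- manifest_features(man)
  expect_length(feats, 105)
  expect_false(anyDuplicated(feats) > 0)
})

test_that("survival binning uses inclusive upper bounds and is monotone", {
  expect_equal(bin_survival_days(c(0, 250, 251, 500, 501, 1800)),
               c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_error(bin_survival_days(1801), class = "radqn_range_error")
  # custom spec: days == first edge -> class 0
  sp <- survival_class_spec(c(100, 200, 300))
  expect_equal(bin_survival_days(100, sp), 0L)
  # monotone nondecreasing over the full range
  days <- 0:1800
  expect_true(all(diff(bin_survival_days(days)) >= 0))
})

test_that("grouped stratified split reproduces printed cohort sizes", {
  # grading cohort: 595 samples (304 vs 291), singleton groups -> 476/119
  tab <- toy_table(n = 595, d = 1, labels = rep(c(0L, 1L), c(304, 291)))
  sp <- split_grouped(tab, fraction = 0.8, seed = 3)
  expect_equal(nrow(sp$train), 476)
  expect_equal(nrow(sp$test), 119)
  # survival cohort: 705 samples -> 564/141
  tab2 <- toy_table(n = 705, d = 1, labels = rep(c(0L, 1L, 2L), c(225, 258, 222)))
  sp2 <- split_grouped(tab2, fraction = 0.8, seed = 9)
  expect_equal(nrow(sp2$train), 564)
  expect_equal(nrow(sp2$test), 141)
  # sizes are seed-invariant for singleton groups
  for (s in c(1, 2, 77)) {
    expect_equal(nrow(split_grouped(tab, 0.8, seed = s)$train), 476)
  }
})

test_that("splits are group-atomic and deterministic under a seed", {
  tab <- toy_table(n = 10, d = 1, labels = rep(0:1, each = 5),
                   groups = rep(c("gA", "gB"), each = 5))
  sp <- split_grouped(tab, fraction = 0.5, seed = 1)
  expect_length(intersect(sp$train$group_id, sp$test$group_id), 0)
  # augmented-style table: copies share their origin group
  big <- toy_table(n = 60, d = 2, labels = rep(0:1, 30),
                   groups = rep(sprintf("g%02d", 1:20), 3))
  for (s in 1:5) {
    spb <- split_grouped(big, 0.8, seed = s)
    expect_length(intersect(spb$train$group_id, spb$test$group_id), 0)
  }
  expect_identical(split_grouped(big, 0.8, seed = 4)$train$sample_id,
                   split_grouped(big, 0.8, seed = 4)$train$sample_id)
})

test_that("k-fold splits partition samples group-atomically with class balance", {
  tab <- toy_table(n = 100, d = 1, labels = rep(0:1, each = 50))
  folds <- kfold_splits(tab, k = 5, seed = 2)
  val_sizes <- vapply(folds, function(f) length(f$validation), integer(1))
  expect_equal(val_sizes, rep(20L, 5))
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_equal(all_val, 1:100)           # every sample validated exactly once
  # class ratios within +/- 1 sample of global ratio
  for (f in folds) {
    n1 <- sum(tab$label[f$validation] == 1)
    expect_lte(abs(n1 - 10), 1)
  }
  # group atomicity with grouped rows
  gtab <- toy_table(n = 30, d = 1, labels = rep(0:1, 15),
                    groups = rep(sprintf("g%d", 1:10), 3))
  gf <- kfold_splits(gtab, k = 3, seed = 1)
  for (f in gf) {
    expect_length(intersect(gtab$group_id[f$train], gtab$group_id[f$validation]), 0)
  }
  expect_error(kfold_splits(gtab, k = 11), class = "radqn_config_error")
})

test_that("z-score normalization fits, transforms, and degrades gracefully", {
  tab <- toy_table(n = 20, d = 3)
  tab$feat3 <- 5                     # constant feature
  norm <- zscore_normalize(tab)
  m <- feature_matrix(norm$table)
  expect_lt(max(abs(colMeans(m))), 1e-10)
  expect_equal(unname(m[, "feat3"]), rep(0, 20))
  expect_equal(sd(m[, "feat1"]), 1, tolerance = 1e-12)
  # transform mode: hand-computed (x - mu) / sigma on held-out rows
  held <- toy_table(n = 4, d = 3, seed = 99)
  held$feat3 <- 7
  out <- zscore_normalize(held, stats = norm$stats)$table
  st <- norm$stats
  expect_equal(out$feat1, (held$feat1 - st$mean[st$feature == "feat1"]) /
                 st$sd[st$feature == "feat1"])
  # namespace mismatch
  bad_stats <- dplyr::mutate(norm$stats, feature = paste0("x", feature))
  expect_error(zscore_normalize(held, stats = bad_stats),
               class = "radqn_schema_error")
})

test_that("modality fusion concatenates selected features with provenance prefixes", {
  flair <- toy_table(n = 5, d = 24, modality = "FLAIR")
  t1ce <- toy_table(n = 5, d = 29, modality = "T1CE", seed = 11)
  fused <- fuse_modalities(list(flair, t1ce))
  expect_length(feature_names(fused), 53)      # 24 + 29 selected features
  expect_equal(nrow(fused), 5)
  expect_equal(fused$modality[1], "FLAIR+T1CE")
  expect_true(all(startsWith(feature_names(fused),
                             c(rep("FLAIR.", 24), rep("T1CE.", 29)))))
  # fusing a table with itself doubles the namespace under disjoint prefixes
  t2 <- dplyr::mutate(flair, modality = "T2")
  double <- fuse_modalities(list(flair, t2))
  expect_length(feature_names(double), 48)
  # empty second mask -> output equals first selection
  m1 <- selection_mask(rep(1, 24), feature_names(flair))
  m0 <- selection_mask(rep(0, 29), feature_names(t1ce))
  only1 <- fuse_modalities(list(flair, t1ce), list(m1, m0))
  expect_equal(feature_names(only1), paste0("FLAIR.", feature_names(flair)))
  # misaligned sample ids
  shuf <- t1ce[c(2:5, 1), ]
  expect_error(fuse_modalities(list(flair, shuf)), class = "radqn_alignment_error")
})

test_that("normalize-then-fuse commutes with fuse-then-per-block-normalize", {
  a <- toy_table(n = 8, d = 3, modality = "FLAIR")
  b <- toy_table(n = 8, d = 2, modality = "T2", seed = 5)
  path1 <- fuse_modalities(list(zscore_normalize(a)$table, zscore_normalize(b)$table))
  path2 <- zscore_normalize(fuse_modalities(list(a, b)))$table
  expect_equal(feature_matrix(path1), feature_matrix(path2), tolerance = 1e-12)
})
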