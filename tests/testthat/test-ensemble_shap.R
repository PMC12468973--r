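ns3 <- c("a", "b", "c")

test_that("majority vote retains features with >= 2 of 3 votes", {
  masks <- list(selection_mask(c(1, 1, 0), ns3, "hho"),
                selection_mask(c(1, 0, 0), ns3, "mgto"),
                selection_mask(c(0, 1, 1), ns3, "zoa"))
  ens <- majority_vote(masks)
  expect_equal(ens$mask, c(1L, 1L, 0L))          # votes 2, 2, 1
  expect_equal(ens$votes, c(2, 2, 1))
  expect_equal(ens$provenance, "ensemble")
  # three identical masks return that mask
  same <- replicate(3, selection_mask(c(1, 0, 1), ns3), simplify = FALSE)
  expect_equal(majority_vote(same)$mask, c(1L, 0L, 1L))
  # unanimity: min_votes = 3 gives the intersection
  expect_equal(majority_vote(masks, min_votes = 3)$mask, c(0L, 0L, 0L))
  # namespace mismatch
  bad <- selection_mask(c(1, 0, 0), c("x", "y", "z"))
  expect_error(majority_vote(list(masks[[1]], masks[[2]], bad)),
               class = "radqn_schema_error")
})

test_that("linear Shapley importances match the closed form", {
  # single feature with values +/-1, mean 0: importance = |w| for weight w
  tab <- toy_table(n = 4, d = 1)
  tab$feat1 <- c(1, -1, 1, -1)
  tab$label <- c(1L, 0L, 1L, 0L)
  fit <- fit_linear_clf(feature_matrix(tab), tab$label, lambda = 1)
  mask <- selection_mask(1, "feat1")
  imp <- shap_importances(fit, tab, mask)
  # phi_i = w (x_i - mean) on the standardized scale; with x = +/-1 and
  # mean 0 the importance collapses to |w| (up to the unit standardization)
  xs <- (tab$feat1 - fit$center) / fit$scale
  expect_equal(imp$importance, mean(abs(fit$weights[, 1] * (xs - mean(xs)))),
               tolerance = 1e-12)
  expect_equal(imp$importance, abs(fit$weights[1, 1]) * mean(abs(xs)),
               tolerance = 1e-12)

  # zero-weight feature has zero importance
  tab2 <- toy_table(n = 20, d = 2, seed = 3)
  tab2$feat2 <- 3.14                      # constant -> zero weight after scaling
  fit2 <- fit_linear_clf(feature_matrix(tab2), tab2$label, lambda = 1)
  imp2 <- shap_importances(fit2, tab2, selection_mask(c(1, 1), c("feat1", "feat2")))
  expect_equal(imp2$importance[imp2$feature == "feat2"], 0, tolerance = 1e-12)

  # invariance to feature reordering (up to permutation)
  tab3 <- toy_table(n = 30, d = 3, seed = 4)
  fit3 <- fit_linear_clf(feature_matrix(tab3), tab3$label)
  imp3 <- shap_importances(fit3, tab3, selection_mask(rep(1, 3), feature_names(tab3)))
  perm <- tab3[, c("sample_id", "group_id", "modality", "label",
                   "feat3", "feat1", "feat2")]
  fitp <- fit_linear_clf(feature_matrix(perm), perm$label)
  impp <- shap_importances(fitp, perm, selection_mask(rep(1, 3), feature_names(perm)))
  expect_equal(impp$importance[match(imp3$feature, impp$feature)],
               imp3$importance, tolerance = 1e-10)
})

test_that("cumulative selection includes the threshold-crossing feature", {
  imp <- tibble::tibble(feature = c("a", "b", "c", "d"),
                        importance = c(0.5, 0.3, 0.15, 0.05),
                        rank = 1:4)
  class(imp) <- c("importance_vector", class(imp))
  sel <- cumulative_select(imp, theta = 0.9)
  expect_equal(selected_features(sel), c("a", "b", "c"))  # cum 0.5, 0.8, 0.95
  # single feature always selected
  one <- imp[1, ]
  expect_equal(sum(cumulative_select(one, theta = 0.99)$mask), 1)
  # ten equal shares, theta = 0.9 -> nine selected (inclusive crossing)
  eq <- tibble::tibble(feature = letters[1:10], importance = rep(1, 10), rank = 1:10)
  class(eq) <- c("importance_vector", class(eq))
  expect_equal(sum(cumulative_select(eq, theta = 0.9)$mask), 9)
  # theta = 1 returns exactly the nonzero-importance features
  mix <- tibble::tibble(feature = letters[1:4], importance = c(2, 1, 1, 0), rank = 1:4)
  class(mix) <- c("importance_vector", class(mix))
  expect_equal(selected_features(cumulative_select(mix, theta = 1)), c("a", "b", "c"))
  # all-zero importances are degenerate
  zero <- tibble::tibble(feature = "a", importance = 0, rank = 1)
  expect_error(cumulative_select(zero), class = "radqn_degenerate_error")
})

test_that("end-to-end selection nests masks and records traces", {
  sep <- separable_table(n_per_class = 25, d = 15)
  cfg <- optimizer_config(pop_size = 8, iterations = 10)
  rep_ <- select_features(sep$table, cfg, seed = 3)
  # containment: final <= ensemble <= union of algorithm masks
  union_mask <- pmin(Reduce(`+`, lapply(rep_$algorithm_masks, `[[`, "mask")), 1)
  expect_true(all(rep_$final$mask <= rep_$ensemble$mask))
  expect_true(all(rep_$ensemble$mask <= union_mask))
  # votes column sums match input masks
  expect_equal(rep_$ensemble$votes,
               Reduce(`+`, lapply(rep_$algorithm_masks, `[[`, "mask")))
  # three traces of length iterations
  expect_length(rep_$traces, 3)
  expect_true(all(vapply(rep_$traces, length, integer(1)) == 10))
  # determinism
  rep2 <- select_features(sep$table, cfg, seed = 3)
  expect_identical(rep2$final$mask, rep_$final$mask)
  # JSON report round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_report(rep_, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$final_mask, rep_$final$mask)
  expect_equal(js$votes, rep_$ensemble$votes)
})

test_that("selected subset classifies at least nearly as well as all features", {
  sep <- separable_table(n_per_class = 30, d = 20)
  rep_ <- select_features(sep$table, optimizer_config(pop_size = 8, iterations = 12),
                          seed = 6)
  full_err <- fitness_error(rep(1, 20), sep$table)
  sel_err <- fitness_error(rep_$final$mask, sep$table)
  expect_lte(sel_err, full_err + 0.05)
})
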