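catalog <- tiny_catalog(2, 3, 3, 2)
schema <- build_schema(catalog, c("am1", "ac1"))

test_that("labels are strict improve-over-threshold", {
  recs <- random_records(catalog, 3, seed = 1)
  recs$yield_percent <- c(65, 55, 0)
  set <- label_records(recs, 55, catalog, schema)
  expect_identical(set$labels, c(1L, 0L, 0L))
  expect_identical(set$threshold_percent, 55)
  recs$yield_percent <- c(0, 0, 0)
  expect_identical(label_records(recs, 10, catalog, schema)$labels, rep(0L, 3))
  expect_error(label_records(recs[0, ], 10, catalog, schema), "empty|no records")
})

test_that("training is deterministic for a fixed seed and respects depth 1", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rbinom(40, 1, 0.4)
  cfg <- model_config(n_models = 8, trees_per_model = 5, max_depth = 1, seed = 9)
  e1 <- train_forest_batch(raw_labeled_set(X, y), cfg)
  e2 <- train_forest_batch(raw_labeled_set(X, y), cfg)
  split_feats <- function(e) unlist(lapply(e$members, function(m)
    lapply(m$trees, function(tr) tr$feature)))
  expect_identical(split_feats(e1), split_feats(e2))
  expect_identical(predict_improvement(e1, X), predict_improvement(e2, X))
  # depth bound: every tree is a single split (3 nodes) or a lone leaf
  for (m in e1$members) for (tr in m$trees) {
    expect_true(length(tr$feature) %in% c(1L, 3L))
    expect_lte(sum(!is.na(tr$feature)), 1L)
  }
  # member i is seeded seed + i: a one-member batch at seed+1 equals member 1
  e3 <- train_forest_batch(raw_labeled_set(X, y),
                           model_config(n_models = 1, trees_per_model = 5,
                                        seed = 9))
  expect_identical(e3$members[[1]]$trees, e1$members[[1]]$trees)
})

test_that("a perfectly separating feature dominates the splits", {
  X <- cbind(sep = rep(c(0, 1), each = 25), noise = rnorm(50))
  y <- rep(c(0L, 1L), each = 25)
  e <- train_forest_batch(raw_labeled_set(X, y),
                          model_config(n_models = 20, trees_per_model = 5,
                                       mtry = 2, seed = 4))
  feats <- unlist(lapply(e$members, function(m)
    lapply(m$trees, function(tr) tr$feature[1])))
  expect_gte(mean(feats == 1, na.rm = TRUE), 0.95)
})

test_that("single-class data yields leaf-only stumps with the empirical rate", {
  X <- matrix(rnorm(20), 10, 2)
  e <- train_forest_batch(raw_labeled_set(X, rep(0L, 10)),
                          model_config(n_models = 3, trees_per_model = 4, seed = 1))
  expect_true(all(predict_improvement(e, X) == 0))
  for (m in e$members) for (tr in m$trees) expect_true(is.na(tr$feature[1]))
})

test_that("predict_improvement routes through leaves as constructed", {
  # single stump: x[2] <= 1.5 -> 0.9, else 0.2
  e <- manual_ensemble(list(list(make_stump(2, 1.5, 0.9, 0.2))), width = 3)
  expect_equal(as.numeric(predict_improvement(e, c(0, 1.0, 0))), 0.9)
  expect_equal(as.numeric(predict_improvement(e, c(0, 2.0, 0))), 0.2)
  # identical members agree; probabilities stay in [0, 1]
  e3 <- manual_ensemble(rep(list(list(make_stump(1, 0, 0.8, 0.1),
                                      make_leaf(0.4))), 3), width = 3)
  P <- predict_improvement(e3, matrix(rnorm(30), 10, 3))
  expect_identical(P[, 1], P[, 2])
  expect_identical(P[, 1], P[, 3])
  expect_true(all(P >= 0 & P <= 1))
  expect_error(predict_improvement(e3, matrix(0, 2, 4)), "width")
})

test_that("pruning removes exactly the trees endorsing a failed condition", {
  # 10 stumps on feature 1, threshold 0.5; failed condition has x[1] = 0,
  # routed left. k = 4 trees classify it positive (left prob > 0.5).
  p_left <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1, 0.45, 0.05)
  trees <- lapply(p_left, function(p) make_stump(1, 0.5, p, 0.0))
  e <- manual_ensemble(list(trees[1:5], trees[6:10]), width = 2)
  failed <- matrix(c(0, 0), 1, 2)
  pruned <- prune_failed(e, failed)
  expect_identical(n_trees(e) - n_trees(pruned), 4L)
  # postcondition: no remaining tree classifies the failed condition positive
  tp <- atlrxn:::tree_probs(pruned, failed)
  expect_true(all(tp$probs <= 0.5))
  # idempotence and identity cases
  expect_identical(prune_failed(pruned, failed), pruned)
  expect_identical(prune_failed(e, NULL), e)
  clean <- manual_ensemble(list(list(make_stump(1, 0.5, 0.1, 0.2))), width = 2)
  expect_identical(prune_failed(clean, failed), clean)
})

test_that("members with no surviving trees are dropped", {
  bad <- list(make_stump(1, 0.5, 0.9, 0.8))   # positive on both sides
  ok <- list(make_stump(1, 0.5, 0.1, 0.1))
  e <- manual_ensemble(list(bad, ok), width = 2, generations = c(0L, 1L))
  pruned <- prune_failed(e, matrix(0, 1, 2))
  expect_identical(n_members(pruned), 1L)
  expect_identical(generation_tags(pruned), 1L)
})

test_that("pruning contract holds on trained ensembles", {
  set.seed(11)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- rbinom(60, 1, 0.5)
  e <- train_forest_batch(raw_labeled_set(X, y),
                          model_config(n_models = 10, trees_per_model = 6,
                                       seed = 2))
  failed <- matrix(rnorm(3 * 5), 3, 5)
  tp <- atlrxn:::tree_probs(e, failed)
  k <- sum(apply(tp$probs > 0.5, 2, any))
  pruned <- prune_failed(e, failed)
  expect_identical(n_trees(e) - n_trees(pruned), as.integer(k))
  expect_identical(prune_failed(pruned, failed), pruned)
  if (n_trees(pruned) > 0)
    expect_true(all(atlrxn:::tree_probs(pruned, failed)$probs <= 0.5))
})

test_that("combining ensembles concatenates members and tags", {
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rbinom(30, 1, 0.5)
  a <- train_forest_batch(raw_labeled_set(X, y),
                          model_config(n_models = 4, trees_per_model = 3, seed = 1),
                          generation = 0L)
  b <- train_forest_batch(raw_labeled_set(X, y),
                          model_config(n_models = 3, trees_per_model = 3, seed = 50),
                          generation = 1L)
  ab <- combine_ensembles(a, b)
  expect_identical(n_members(ab), 7L)
  expect_identical(generation_tags(ab),
                   c(generation_tags(a), generation_tags(b)))
  expect_identical(combine_ensembles(a, atlrxn:::empty_ensemble(4L))$members,
                   a$members)
  expect_error(combine_ensembles(a, manual_ensemble(list(list(make_leaf(0.5))),
                                                    width = 5)), "width")
})

test_that("descriptor usage counts split classes correctly", {
  # tiny schema layout: substrate 1+1, ligand 2, solvent 2, precat 2, ions
  lig <- which(schema$class_of_feature == "ligand")
  sol <- which(schema$class_of_feature == "solvent")
  pre <- which(schema$class_of_feature == "precatalyst")
  trees <- list(make_stump(lig[1], 0, 0.9, 0.1), make_stump(lig[2], 0, 0.9, 0.1),
                make_stump(sol[1], 0, 0.9, 0.1), make_stump(pre[1], 0, 0.9, 0.1))
  e <- manual_ensemble(list(trees), width = schema$width)
  u <- descriptor_usage(e, schema)
  expect_equal(sum(u), 1, tolerance = 1e-12)
  expect_equal(unname(u[c("ligand", "solvent", "precatalyst")]),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(u["substrate"]), 0)
  # all-ligand ensemble
  e2 <- manual_ensemble(list(list(make_stump(lig[1], 0, 1, 0),
                                  make_stump(lig[2], 1, 1, 0))),
                        width = schema$width)
  expect_equal(unname(descriptor_usage(e2, schema)["ligand"]), 1.0)
  # by generation: rows sum to 1; leaf-only generation contributes zeros
  e3 <- manual_ensemble(list(trees, list(make_leaf(0.3))),
                        width = schema$width, generations = c(0L, 1L))
  ug <- descriptor_usage(e3, schema, by_generation = TRUE)
  expect_equal(sum(ug["gen0", ]), 1, tolerance = 1e-12)
  expect_equal(sum(ug["gen1", ]), 0)
})

test_that("ensemble JSON round trip preserves predictions exactly", {
  set.seed(5)
  X <- matrix(rnorm(40 * 4), 40, 4)
  e <- train_forest_batch(raw_labeled_set(X, rbinom(40, 1, 0.5)),
                          model_config(n_models = 4, trees_per_model = 3,
                                       max_depth = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(e, path)
  back <- read_ensemble(path)
  expect_identical(generation_tags(back), generation_tags(e))
  expect_identical(n_trees(back), n_trees(e))
  expect_identical(predict_improvement(back, X), predict_improvement(e, X))
})
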