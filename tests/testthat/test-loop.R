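catalog <- tiny_catalog(2, 3, 3, 2)
schema <- build_schema(catalog, c("am1", "ac1"))
candidates <- enumerate_space(catalog)

trained_member <- function(seed = 1, n_models = 1) {
  recs <- random_records(catalog, 30, seed = seed)
  train_forest_batch(label_records(recs, 50, catalog, schema),
                     model_config(n_models = n_models, trees_per_model = 5,
                                  seed = seed))
}

test_that("identical members vote unanimously for their top-N", {
  one <- trained_member(seed = 2)
  trip <- atlrxn:::new_ensemble(rep(one$members, 3), one$width)
  N <- 4L
  vs <- vote_select(trip, candidates, schema, catalog, N = N, batch_size = N)
  p <- predict_improvement(one, featurize(candidates, c("am1", "ac1"),
                                          schema, catalog))[, 1]
  expected <- candidates[order(-p, seq_along(p))[1:N], ]
  rownames(expected) <- NULL
  expect_identical(vs$batch, expected)
  expect_true(all(vs$batch_votes == 3L))
})

test_that("1-member vote_select equals exhaustive probability ranking", {
  set.seed(21)
  for (rep in 1:4) {
    sizes <- sample(2:6, 4, replace = TRUE)   # pools up to 1296 <= 2000
    cat_r <- tiny_catalog(sizes[1], sizes[2], sizes[3], sizes[4], seed = rep)
    sch_r <- build_schema(cat_r, c("am1", "ac1"))
    pool <- enumerate_space(cat_r)
    recs <- random_records(cat_r, 40, seed = rep + 10)
    e1 <- train_forest_batch(label_records(recs, 50, cat_r, sch_r),
                             model_config(n_models = 1, trees_per_model = 8,
                                          seed = rep))
    bs <- sample(2:5, 1)
    vs <- vote_select(e1, pool, sch_r, cat_r, N = bs, batch_size = bs)
    # oracle: full stable sort of the single member's probabilities
    p <- predict_improvement(e1, featurize(pool, c("am1", "ac1"), sch_r, cat_r))[, 1]
    oracle <- pool[order(-p, seq_along(p))[seq_len(bs)], ]
    rownames(oracle) <- NULL
    expect_identical(vs$batch, oracle)
  }
})

test_that("vote totals are conserved and exclusion is respected", {
  e <- trained_member(seed = 3, n_models = 6)
  N <- 3L
  vs <- vote_select(e, candidates, schema, catalog, N = N, batch_size = 4)
  expect_identical(sum(vs$tally$votes), 6L * N)
  excl <- candidates[1:30, ]
  vs2 <- vote_select(e, candidates, schema, catalog, N = N, batch_size = 4,
                     exclude = excl)
  expect_identical(nrow(merge(vs2$batch, excl)), 0L)
  # exhaustion: fewer remaining candidates than batch_size
  expect_warning(
    vs3 <- vote_select(e, candidates, schema, catalog, N = 2,
                       batch_size = 10, exclude = candidates[-(1:5), ]),
    "fewer")
  expect_identical(vs3$status, "exhausted")
  expect_identical(nrow(vs3$batch), 5L)
  expect_error(vote_select(e, candidates, schema, catalog, N = 2,
                           batch_size = 2, exclude = candidates),
               "no candidates")
})

make_test_campaign <- function(n_iterations = 2, batch_size = 3, seed = 5,
                               threshold = 40, oracle_landscape = NULL,
                               ...) {
  landscape <- oracle_landscape %||%
    make_landscape_pair(catalog, landscape_spec(noise_sd = 2), seed = 8)$target
  src <- random_records(catalog, 25, pair = c("am2", "ac2"), seed = 6)
  src$yield_percent <- eval_yield(landscape, src[, names(candidates)])
  cfg <- campaign_config(batch_size = batch_size, n_iterations = n_iterations,
                         threshold_percent = threshold, seed = seed,
                         model = list(n_models = 10, trees_per_model = 4), ...)
  run_campaign(catalog, c("am1", "ac1"), src, make_oracle(landscape), cfg)
}

test_that("campaigns are deterministic and never repeat a condition", {
  t1 <- make_test_campaign()
  t2 <- make_test_campaign()
  expect_identical(t1$iterations, t2$iterations)
  proposed <- do.call(rbind, lapply(t1$iterations, `[[`, "proposed"))
  expect_identical(nrow(proposed), 2L * 3L)
  expect_identical(anyDuplicated(proposed), 0L)
  expect_identical(length(t1$iterations), 2L)
  # best-so-far is non-decreasing
  bsf <- vapply(t1$iterations, `[[`, numeric(1), "best_so_far")
  expect_true(all(diff(bsf) >= 0))
})

test_that("failure and success paths move best-so-far correctly", {
  flat <- make_landscape(catalog, base = 10)   # everything yields 10
  tr <- make_test_campaign(threshold = 40, oracle_landscape = flat)
  expect_identical(tr$best_so_far, 40)   # nothing beats the baseline
  expect_true(all(vapply(tr$iterations, `[[`, numeric(1), "best_so_far") == 40))
  # pruning can only shrink the ensemble
  for (it in tr$iterations)
    expect_lte(it$trees_after_prune, it$trees_before_prune)
  rich <- make_landscape(catalog, base = 90)
  tr2 <- make_test_campaign(threshold = 40, oracle_landscape = rich)
  expect_gt(tr2$best_so_far, 40)
})

test_that("n_iterations = 0 leaves only the source stage", {
  tr <- make_test_campaign(n_iterations = 0)
  expect_identical(length(tr$iterations), 0L)
  expect_identical(generation_tags(tr$ensemble), rep(0L, 10L))
})

test_that("fixed reagents restrict every proposal and the pool", {
  tr <- make_test_campaign(fixed = list(ligand = "L2"))
  proposed <- do.call(rbind, lapply(tr$iterations, `[[`, "proposed"))
  expect_true(all(proposed$ligand == "L2"))
})

test_that("oracle failures are recorded but excluded from labeling", {
  landscape <- make_landscape(catalog, base = 50)
  flaky <- function(conds) {
    y <- eval_yield(landscape, conds)
    y[1] <- NA
    y
  }
  src <- random_records(catalog, 25, seed = 6)
  cfg <- campaign_config(batch_size = 3, n_iterations = 1,
                         threshold_percent = 40, seed = 5,
                         model = list(n_models = 5, trees_per_model = 3))
  tr <- run_campaign(catalog, c("am1", "ac1"), src, flaky, cfg)
  expect_identical(sum(is.na(tr$iterations[[1]]$observed_yield)), 1L)
  expect_identical(nrow(tr$target_records), 2L)
})

test_that("suggest_next replays records and avoids evaluated conditions", {
  src <- random_records(catalog, 25, pair = c("am2", "ac2"), seed = 6)
  tgt <- random_records(catalog, 3, pair = c("am1", "ac1"),
                        domain = "target", iteration = 1L, seed = 7)
  cfg <- campaign_config(batch_size = 3, n_iterations = 3,
                         threshold_percent = 50, seed = 5,
                         model = list(n_models = 8, trees_per_model = 3))
  vs <- suggest_next(catalog, c("am1", "ac1"), rbind(src, tgt), cfg)
  expect_identical(nrow(vs$batch), 3L)
  expect_identical(nrow(merge(vs$batch, tgt[, names(candidates)])), 0L)
  expect_identical(sort(unique(vs$provenance)), c(0L, 1L))
})

test_that("stopping hint is (number of varied classes) - 1", {
  expect_identical(stopping_hint(4), 3L)
  expect_identical(stopping_hint(2), 1L)
  expect_identical(stopping_hint(5), 4L)
  expect_error(stopping_hint(1), "at least 2")
})
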