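#' Benchmark acquisition strategies on a synthetic landscape pair
#'
#' Replays the campaign protocol and baseline strategies against a
#' ground-truth landscape pair. Per replicate, a fresh biased source dataset
#' is drawn from the source landscape, the classification threshold is set
#' to the target-landscape (noiseless) yield of the best source condition —
#' the "previously optimized condition" — and every strategy spends the same
#' budget of `n_iterations` batches of `batch_size` target reactions.
#'
#' Strategies:
#' \describe{
#'   \item{atl}{the full protocol: transferred source ensemble, voting,
#'     pruning, generational updates.}
#'   \item{random}{uniform random batches without replacement.}
#'   \item{pure_active}{no source transfer: random first batch, then
#'     vote/prune/retrain on target data only.}
#'   \item{pure_transfer}{the source ensemble votes every round but is never
#'     pruned or updated.}
#'   \item{oracle_greedy}{cheats by reading the noiseless target landscape;
#'     upper-bound sanity row that finds the landscape maximum in
#'     iteration 1.}
#' }
#'
#' @param pair an [make_landscape_pair()] result.
#' @param catalog the catalog the pair was built on.
#' @param strategies character vector of strategy names.
#' @param n_iterations,batch_size the budget (total = product).
#' @param replicates number of replicate campaigns per strategy.
#' @param seed base seed; replicate `r` uses `seed + r` everywhere, so
#'   strategies are compared on common random numbers.
#' @param model model parameter list as in [campaign_config()].
#' @param sampling source-dataset sampling spec, see
#'   [source_dataset_from_landscape()].
#' @param threshold NULL (default: per replicate, the target-landscape
#'   noiseless yield of the best source condition — the previously
#'   optimized condition) or a fixed percent applied to every replicate;
#'   fix it when comparing across landscape-pair specs so that baseline
#'   difficulty does not vary with the spec.
#' @return data.frame with columns `strategy`, `replicate`, `iteration`,
#'   `best_yield` (cumulative best observed assay yield, percent).
#' @export
benchmark_strategies <- function(pair, catalog,
                                 strategies = c("atl", "random", "pure_active",
                                                "pure_transfer"),
                                 n_iterations = 3L, batch_size = 6L,
                                 replicates = 100L, seed = 1L,
                                 model = list(), sampling = list(),
                                 threshold = NULL) {
  stopifnot(inherits(pair, "atl_landscape_pair"))
  known <- c("atl", "random", "pure_active", "pure_transfer", "oracle_greedy")
  bad <- setdiff(strategies, known)
  if (length(bad)) stop("unknown strategy: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- vector("list", length(strategies) * replicates)
  k <- 0L
  for (r in seq_len(replicates)) {
    rep_seed <- as.integer(seed) + r
    src <- source_dataset_from_landscape(pair$source, catalog, sampling,
                                         seed = rep_seed)
    thr <- if (is.null(threshold)) {
      baseline <- src[which.max(src$yield_percent), REAGENT_CLASSES]
      eval_yield(pair$target, baseline, noisy = FALSE)
    } else as.numeric(threshold)
    for (s in strategies) {
      best <- run_strategy(s, pair, catalog, src, thr, n_iterations,
                           batch_size, rep_seed, model)
      k <- k + 1L
      out[[k]] <- data.frame(strategy = s, replicate = r,
                             iteration = seq_len(n_iterations),
                             best_yield = best)
    }
  }
  do.call(rbind, out)
}

#' Median and interquartile summary of a benchmark table
#'
#' @param results output of [benchmark_strategies()].
#' @return data.frame: strategy, iteration, median, q25, q75 of best yield.
#' @export
summarize_benchmark <- function(results) {
  sp <- split(results$best_yield,
              list(strategy = results$strategy, iteration = results$iteration))
  keys <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  data.frame(strategy = keys[, 1], iteration = as.integer(keys[, 2]),
             median = vapply(sp, median, numeric(1)),
             q25 = vapply(sp, function(v) unname(stats::quantile(v, 0.25)),
                          numeric(1)),
             q75 = vapply(sp, function(v) unname(stats::quantile(v, 0.75)),
                          numeric(1)),
             row.names = NULL)
}

run_strategy <- function(strategy, pair, catalog, src, threshold,
                         n_iterations, batch_size, rep_seed, model) {
  target <- pair$target
  switch(strategy,
         atl = strat_atl(pair, catalog, src, threshold, n_iterations,
                         batch_size, rep_seed, model),
         random = strat_random(target, catalog, n_iterations, batch_size,
                               rep_seed),
         pure_active = strat_pure_active(target, catalog, threshold,
                                         n_iterations, batch_size, rep_seed,
                                         model),
         pure_transfer = strat_pure_transfer(pair, catalog, src, threshold,
                                             n_iterations, batch_size,
                                             rep_seed, model),
         oracle_greedy = strat_oracle_greedy(target, catalog, n_iterations,
                                             batch_size, rep_seed))
}

cumbest <- function(per_iter_max) cummax(per_iter_max)

strat_atl <- function(pair, catalog, src, threshold, n_iterations, batch_size,
                      rep_seed, model) {
  cfg <- campaign_config(batch_size = batch_size, n_iterations = n_iterations,
                         threshold_percent = threshold, model = model,
                         seed = rep_seed)
  tr <- run_campaign(catalog, pair$target$substrate_pair, src,
                     make_oracle(pair$target), cfg)
  per_iter <- vapply(tr$iterations, function(it)
    max(it$observed_yield, na.rm = TRUE), numeric(1))
  pad_iterations(cumbest(per_iter), n_iterations)
}

strat_random <- function(target, catalog, n_iterations, batch_size, rep_seed) {
  set.seed(rep_seed)
  candidates <- enumerate_space(catalog)
  picks <- sample.int(nrow(candidates), n_iterations * batch_size)
  per_iter <- vapply(seq_len(n_iterations), function(g) {
    batch <- candidates[picks[(g - 1L) * batch_size + seq_len(batch_size)], ,
                        drop = FALSE]
    max(eval_yield(target, batch, noisy = TRUE))
  }, numeric(1))
  cumbest(per_iter)
}

strat_pure_active <- function(target, catalog, threshold, n_iterations,
                              batch_size, rep_seed, model) {
  set.seed(rep_seed)
  pairc <- target$substrate_pair
  schema <- build_schema(catalog, pairc)
  candidates <- enumerate_space(catalog)
  cand_X <- featurize(candidates, pairc, schema, catalog)
  mdl <- modifyList(list(n_models = 100L, trees_per_model = 10L, max_depth = 1L,
                         mtry = NULL, min_leaf = 1L), model)
  excluded <- rep(FALSE, nrow(candidates))
  ensemble <- NULL
  records <- NULL
  per_iter <- numeric(n_iterations)
  for (g in seq_len(n_iterations)) {
    if (is.null(ensemble)) {
      idx <- which(!excluded)
      batch <- candidates[idx[sample.int(length(idx), batch_size)], ,
                          drop = FALSE]
    } else {
      batch <- vote_select(ensemble, candidates, schema, catalog,
                           N = batch_size, batch_size = batch_size,
                           exclude = candidates[excluded, , drop = FALSE],
                           features = cand_X)$batch
    }
    yields <- eval_yield(target, batch, noisy = TRUE)
    per_iter[g] <- max(yields)
    excluded <- excluded | cond_key(candidates) %in% cond_key(batch)
    block <- cbind(data.frame(amine_id = pairc[1], acid_id = pairc[2],
                              stringsAsFactors = FALSE),
                   batch,
                   data.frame(yield_percent = yields, domain = "target",
                              iteration = g, stringsAsFactors = FALSE))
    records <- rbind(records, block)
    failed <- block[block$yield_percent <= threshold, , drop = FALSE]
    if (!is.null(ensemble) && nrow(failed) > 0L)
      ensemble <- prune_failed(ensemble,
                               featurize_records(failed, schema, catalog))
    mcfg <- do.call(model_config, c(mdl, list(seed = rep_seed + g * mdl$n_models)))
    gen <- train_forest_batch(label_records(records, threshold, catalog, schema),
                              mcfg, generation = g)
    ensemble <- if (is.null(ensemble) || n_members(ensemble) == 0L) gen
    else combine_ensembles(ensemble, gen)
  }
  cumbest(per_iter)
}

strat_pure_transfer <- function(pair, catalog, src, threshold, n_iterations,
                                batch_size, rep_seed, model) {
  set.seed(rep_seed)
  target <- pair$target
  pairc <- target$substrate_pair
  schema <- build_schema(catalog, pairc)
  candidates <- enumerate_space(catalog)
  cand_X <- featurize(candidates, pairc, schema, catalog)
  mcfg <- do.call(model_config,
                  c(modifyList(list(n_models = 100L, trees_per_model = 10L,
                                    max_depth = 1L, mtry = NULL, min_leaf = 1L),
                               model),
                    list(seed = rep_seed)))
  labeled <- label_records(src, threshold, catalog, schema)
  ensemble <- train_forest_batch(labeled, mcfg, generation = 0L)
  excluded <- cond_key(candidates) %in%
    cond_key(src[src$amine_id == pairc[1] & src$acid_id == pairc[2], ])
  per_iter <- numeric(n_iterations)
  for (g in seq_len(n_iterations)) {
    batch <- vote_select(ensemble, candidates, schema, catalog,
                         N = batch_size, batch_size = batch_size,
                         exclude = candidates[excluded, , drop = FALSE],
                         features = cand_X)$batch
    per_iter[g] <- max(eval_yield(target, batch, noisy = TRUE))
    excluded <- excluded | cond_key(candidates) %in% cond_key(batch)
  }
  cumbest(per_iter)
}

strat_oracle_greedy <- function(target, catalog, n_iterations, batch_size,
                                rep_seed) {
  set.seed(rep_seed)
  candidates <- enumerate_space(catalog)
  truth <- eval_yield(target, candidates, noisy = FALSE)
  ord <- order(-truth, seq_along(truth))
  per_iter <- vapply(seq_len(n_iterations), function(g) {
    batch <- candidates[ord[(g - 1L) * batch_size + seq_len(batch_size)], ,
                        drop = FALSE]
    max(eval_yield(target, batch, noisy = TRUE))
  }, numeric(1))
  cumbest(per_iter)
}

pad_iterations <- function(v, n) {
  if (length(v) >= n) return(v[seq_len(n)])
  c(v, rep(if (length(v)) v[length(v)] else NA_real_, n - length(v)))
}
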