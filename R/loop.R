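#' Campaign configuration
#'
#' Settings for a closed-loop or human-in-the-loop optimization campaign.
#' Defaults follow the protocol's practical HTE setting: batches of 6
#' reactions, 3 iterations, each of the 100 ensemble members voting for its
#' top `batch_size` candidates, a classification threshold fixed at the
#' previously optimized condition's yield.
#'
#' @param batch_size reactions per iteration (plate-friendly: 3, 6 or 24).
#' @param votes_per_model N, candidates each member votes for; default
#'   `batch_size`.
#' @param n_iterations number of propose/observe/update rounds.
#' @param threshold_percent baseline yield (percent) a condition must beat.
#' @param source_threshold_percent threshold used to label the source
#'   records; default `threshold_percent`.
#' @param model list of [model_config()] parameters (without `seed`):
#'   `n_models`, `trees_per_model`, `max_depth`, `mtry`, `min_leaf`.
#' @param fixed optional named list pinning reagent classes (e.g.
#'   `list(ligand = "L1")`), restricting the candidate pool.
#' @param seed campaign seed; generation `g`, member `i` trains with
#'   `seed + g * n_models + i`, and all other randomness (oracle noise)
#'   flows from `set.seed(seed)`.
#' @param allow_repeats propose conditions already evaluated (default FALSE).
#' @param ratchet_threshold raise the threshold to the best observed yield
#'   after each iteration (default FALSE: fixed threshold).
#' @param prune_scope prune on this batch's failures only (`"batch"`,
#'   default) or on all failures so far (`"cumulative"`).
#' @param train_window train each new generation on all target records so
#'   far (`"cumulative"`, default) or only the newest batch
#'   (`"latest_batch"`).
#' @return a `campaign_config` list.
#' @export
campaign_config <- function(batch_size = 6L, votes_per_model = NULL,
                            n_iterations = 3L, threshold_percent,
                            source_threshold_percent = NULL,
                            model = list(), fixed = NULL, seed = 1L,
                            allow_repeats = FALSE, ratchet_threshold = FALSE,
                            prune_scope = c("batch", "cumulative"),
                            train_window = c("cumulative", "latest_batch")) {
  mdl <- modifyList(list(n_models = 100L, trees_per_model = 10L, max_depth = 1L,
                         mtry = NULL, min_leaf = 1L), model)
  cfg <- list(batch_size = as.integer(batch_size),
              votes_per_model = as.integer(votes_per_model %||% batch_size),
              n_iterations = as.integer(n_iterations),
              threshold_percent = as.numeric(threshold_percent),
              source_threshold_percent =
                as.numeric(source_threshold_percent %||% threshold_percent),
              model = mdl, fixed = fixed, seed = as.integer(seed),
              allow_repeats = isTRUE(allow_repeats),
              ratchet_threshold = isTRUE(ratchet_threshold),
              prune_scope = match.arg(prune_scope),
              train_window = match.arg(train_window))
  stopifnot(cfg$batch_size >= 1L, cfg$votes_per_model >= 1L,
            cfg$n_iterations >= 0L, !is.na(cfg$threshold_percent))
  structure(cfg, class = "campaign_config")
}

cond_key <- function(conditions)
  do.call(paste, c(conditions[REAGENT_CLASSES], sep = "\r"))

#' Vote-based batch selection
#'
#' Each ensemble member awards one vote to each of its top-N candidates by
#' predicted improvement probability (ties within a member broken by
#' enumeration order); the batch is the `batch_size` candidates with the
#' most votes, ties broken by mean predicted probability across members,
#' then enumeration order. Conditions in `exclude` are never proposed.
#'
#' @param ensemble an `atl_ensemble` with at least one member.
#' @param candidates data.frame of conditions (enumeration order defines
#'   tie-breaking).
#' @param schema,catalog featurization context.
#' @param N votes per member.
#' @param batch_size conditions to propose.
#' @param exclude data.frame of conditions to exclude (or NULL).
#' @param features optional precomputed feature matrix aligned with
#'   `candidates` rows (avoids re-featurizing large pools).
#' @return list with `batch` (data.frame of proposed conditions), `tally`
#'   (data.frame: condition columns, `votes`, `mean_prob`, every candidate
#'   that received at least one vote, vote order), `status` (`"ok"` or
#'   `"exhausted"` when fewer candidates than `batch_size` remained) and
#'   `provenance` (generation tags of the voting members).
#' @export
vote_select <- function(ensemble, candidates, schema, catalog, N, batch_size,
                        exclude = NULL, features = NULL) {
  stopifnot(n_members(ensemble) >= 1L, N >= 1L, batch_size >= 1L)
  keep <- rep(TRUE, nrow(candidates))
  if (!is.null(exclude) && NROW(exclude) > 0L)
    keep <- !(cond_key(candidates) %in% cond_key(exclude))
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("no candidates remain after exclusion", call. = FALSE)
  status <- "ok"
  if (length(idx) < batch_size) {
    warning("fewer remaining candidates than batch_size; proposing all ",
            length(idx), call. = FALSE)
    status <- "exhausted"
    batch_size <- length(idx)
  }
  X <- if (is.null(features))
    featurize(candidates[idx, , drop = FALSE], schema$substrate_pair, schema, catalog)
  else as_feature_matrix(features[idx, , drop = FALSE])
  check_width(ensemble, X)
  P <- cpp_member_probs(X, ensemble$members)
  top <- cpp_top_n(P, min(N, length(idx)))
  votes <- tabulate(top, nbins = length(idx))
  mean_prob <- rowMeans(P)
  ord <- order(-votes, -mean_prob, seq_along(idx))
  pick <- ord[seq_len(batch_size)]
  voted <- ord[votes[ord] > 0L]
  tally <- cbind(candidates[idx[voted], , drop = FALSE],
                 votes = votes[voted], mean_prob = mean_prob[voted])
  rownames(tally) <- NULL
  batch <- candidates[idx[pick], , drop = FALSE]
  rownames(batch) <- NULL
  list(batch = batch, tally = tally, status = status,
       provenance = generation_tags(ensemble),
       batch_votes = votes[pick], batch_mean_prob = mean_prob[pick])
}

#' Initialize a campaign state
#'
#' Builds the featurization schema, enumerates (and featurizes) the
#' candidate pool, trains the generation-0 source ensemble on the source
#' records, and marks already-evaluated conditions for exclusion.
#'
#' @param catalog a [reagent_catalog()].
#' @param substrate_pair (amine id, acid id) target pair.
#' @param source_records source-domain reaction records.
#' @param config a [campaign_config()].
#' @return a campaign state list; pass to [run_iteration()].
#' @export
campaign_init <- function(catalog, substrate_pair, source_records, config) {
  stopifnot(inherits(config, "campaign_config"))
  schema <- build_schema(catalog, substrate_pair)
  candidates <- enumerate_space(catalog, config$fixed)
  cand_X <- featurize(candidates, substrate_pair, schema, catalog)
  source_records <- reaction_records(source_records, catalog)
  if (nrow(source_records) == 0L)
    stop("source records must be non-empty", call. = FALSE)
  mcfg <- do.call(model_config, c(config$model, list(seed = config$seed)))
  labeled <- label_records(source_records, config$source_threshold_percent,
                           catalog, schema)
  ensemble <- train_forest_batch(labeled, mcfg, generation = 0L)
  excluded <- rep(FALSE, nrow(candidates))
  if (!config$allow_repeats) {
    same_pair <- source_records$amine_id == substrate_pair[1] &
      source_records$acid_id == substrate_pair[2]
    excluded <- cond_key(candidates) %in% cond_key(source_records[same_pair, ])
  }
  list(catalog = catalog, schema = schema, config = config,
       candidates = candidates, cand_X = cand_X, excluded = excluded,
       ensemble = ensemble, source_records = source_records,
       target_records = source_records[0, ],
       threshold = config$threshold_percent,
       best_so_far = config$threshold_percent,
       iteration = 0L, trace = list(), status = "running")
}

#' Run one campaign iteration
#'
#' One full protocol round: propose a batch by ensemble voting, observe
#' yields from the oracle, label against the threshold, prune trees that
#' endorsed this batch's failures, train a new generation on the collected
#' target data, and merge it into the ensemble.
#'
#' @param state a campaign state from [campaign_init()].
#' @param oracle function taking a data.frame of conditions and returning
#'   observed assay yields in percent (NA = failed measurement, excluded
#'   from labeling), e.g. [make_oracle()].
#' @return the updated state, with a new entry appended to `state$trace`.
#' @export
run_iteration <- function(state, oracle) {
  cfg <- state$config
  if (all(state$excluded)) {
    state$status <- "pool_exhausted"
    return(state)
  }
  state$iteration <- state$iteration + 1L
  vs <- vote_select(state$ensemble, state$candidates, state$schema,
                    state$catalog, N = cfg$votes_per_model,
                    batch_size = cfg$batch_size,
                    exclude = state$candidates[state$excluded, , drop = FALSE],
                    features = state$cand_X)
  batch <- vs$batch
  yields <- as.numeric(oracle(batch))
  stopifnot(length(yields) == nrow(batch))
  ok <- !is.na(yields)

  batch_records <- cbind(
    data.frame(amine_id = state$schema$substrate_pair[1],
               acid_id = state$schema$substrate_pair[2],
               stringsAsFactors = FALSE),
    batch,
    data.frame(yield_percent = yields, domain = "target",
               iteration = state$iteration, stringsAsFactors = FALSE))
  state$target_records <- rbind(state$target_records,
                                reaction_records(batch_records[ok, , drop = FALSE]))
  if (!cfg$allow_repeats)
    state$excluded <- state$excluded | (cond_key(state$candidates) %in% cond_key(batch))

  trees_before <- n_trees(state$ensemble)
  fail_pool <- if (cfg$prune_scope == "cumulative") state$target_records
  else batch_records[ok, , drop = FALSE]
  failed <- fail_pool[fail_pool$yield_percent <= state$threshold, , drop = FALSE]
  if (nrow(failed) > 0L)
    state$ensemble <- prune_failed(
      state$ensemble, featurize_records(failed, state$schema, state$catalog))
  trees_after <- n_trees(state$ensemble)

  train_set <- if (cfg$train_window == "cumulative") state$target_records
  else state$target_records[state$target_records$iteration == state$iteration, ,
                            drop = FALSE]
  if (nrow(train_set) > 0L) {
    mcfg <- do.call(model_config, c(
      cfg$model,
      list(seed = cfg$seed + state$iteration * cfg$model$n_models)))
    labeled <- label_records(train_set, state$threshold, state$catalog, state$schema)
    gen <- train_forest_batch(labeled, mcfg, generation = state$iteration)
    state$ensemble <- combine_ensembles(state$ensemble, gen)
  }

  if (any(ok)) state$best_so_far <- max(state$best_so_far, yields[ok])
  if (cfg$ratchet_threshold && any(ok))
    state$threshold <- max(state$threshold, yields[ok])

  state$trace[[length(state$trace) + 1L]] <- list(
    iteration = state$iteration, status = vs$status,
    proposed = batch, votes = vs$batch_votes,
    mean_prob = vs$batch_mean_prob, observed_yield = yields,
    threshold = state$threshold,
    trees_before_prune = trees_before, trees_after_prune = trees_after,
    members = n_members(state$ensemble), best_so_far = state$best_so_far)
  if (vs$status == "exhausted") state$status <- "pool_exhausted"
  state
}

#' Run a full active-transfer-learning campaign
#'
#' Trains the source ensemble, then iterates propose / observe / prune /
#' retrain / combine for `config$n_iterations` rounds (ending early with
#' status `"pool_exhausted"` if the candidate pool runs out).
#'
#' @inheritParams campaign_init
#' @param oracle yield oracle, as in [run_iteration()].
#' @return an `atl_campaign_trace`: list with `iterations` (one entry per
#'   round), `best_so_far`, `final state` fields.
#' @export
run_campaign <- function(catalog, substrate_pair, source_records, oracle, config) {
  set.seed(config$seed)
  state <- campaign_init(catalog, substrate_pair, source_records, config)
  for (i in seq_len(config$n_iterations)) {
    if (state$status != "running") break
    state <- run_iteration(state, oracle)
  }
  if (state$status == "running") state$status <- "done"
  structure(list(iterations = state$trace,
                 best_so_far = state$best_so_far,
                 threshold = state$threshold,
                 status = state$status,
                 substrate_pair = state$schema$substrate_pair,
                 config = unclass(config),
                 ensemble = state$ensemble,
                 target_records = state$target_records),
            class = "atl_campaign_trace")
}

#' @export
print.atl_campaign_trace <- function(x, ...) {
  cat(sprintf("<atl_campaign_trace> %d iteration(s), status %s, best yield %.1f%% (threshold %.1f%%)\n",
              length(x$iterations), x$status, x$best_so_far, x$threshold))
  for (it in x$iterations)
    cat(sprintf("  iter %d: batch %d, best observed %.1f%%, trees %d -> %d, best so far %.1f%%\n",
                it$iteration, nrow(it$proposed), max(c(it$observed_yield, -Inf), na.rm = TRUE),
                it$trees_before_prune, it$trees_after_prune, it$best_so_far))
  invisible(x)
}

#' Tabulate a campaign trace
#'
#' @param x an `atl_campaign_trace`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame, one row per iteration.
#' @export
as.data.frame.atl_campaign_trace <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  if (length(x$iterations) == 0L)
    return(data.frame(iteration = integer(0), best_observed = numeric(0),
                      best_so_far = numeric(0), trees_before_prune = integer(0),
                      trees_after_prune = integer(0)))
  do.call(rbind, lapply(x$iterations, function(it)
    data.frame(iteration = it$iteration,
               best_observed = suppressWarnings(max(it$observed_yield, na.rm = TRUE)),
               best_so_far = it$best_so_far,
               trees_before_prune = it$trees_before_prune,
               trees_after_prune = it$trees_after_prune)))
}

#' Write a campaign trace as line-delimited JSON
#'
#' One JSON object per iteration; deterministic byte-for-byte for a fixed
#' seed and oracle (no timestamps).
#'
#' @param trace an `atl_campaign_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, open = "wb")   # binary: fixed \n line endings
  on.exit(close(con))
  hdr <- list(type = "campaign", status = trace$status,
              substrate_pair = trace$substrate_pair,
              best_so_far = trace$best_so_far, threshold = trace$threshold,
              n_iterations = length(trace$iterations))
  writeLines(jsonlite::toJSON(hdr, digits = I(17), auto_unbox = TRUE), con, sep = "\n")
  for (it in trace$iterations)
    writeLines(jsonlite::toJSON(it, digits = I(17), auto_unbox = TRUE,
                                dataframe = "rows"), con, sep = "\n")
  invisible(path)
}

#' Propose the next batch from reaction records on disk
#'
#' The human-in-the-loop mode: reconstructs the campaign state from a
#' record table (source records train generation 0; target records at
#' iterations 1..G replay pruning and retraining in order) and returns the
#' next proposed batch.
#'
#' @inheritParams campaign_init
#' @param records all reaction records so far (source and target rows).
#' @return a [vote_select()] result for the next batch.
#' @export
suggest_next <- function(catalog, substrate_pair, records, config) {
  records <- reaction_records(records, catalog)
  src <- records[records$domain == "source", , drop = FALSE]
  tgt <- records[records$domain == "target", , drop = FALSE]
  state <- campaign_init(catalog, substrate_pair, src, config)
  if (nrow(tgt) > 0L) {
    if (any(tgt$iteration < 1L))
      stop("target records must have iteration >= 1", call. = FALSE)
    # Replay observed batches verbatim instead of re-proposing: feed each
    # recorded iteration through the same observe/prune/retrain path.
    for (g in sort(unique(tgt$iteration))) {
      block <- tgt[tgt$iteration == g, , drop = FALSE]
      state$iteration <- g - 1L
      state <- replay_observe(state, block)
    }
  }
  vote_select(state$ensemble, state$candidates, state$schema, state$catalog,
              N = config$votes_per_model, batch_size = config$batch_size,
              exclude = rbind(
                state$candidates[state$excluded, , drop = FALSE],
                if (!config$allow_repeats) tgt[, REAGENT_CLASSES]),
              features = state$cand_X)
}

# Observe a recorded batch: the prune/retrain/combine half of run_iteration.
replay_observe <- function(state, block) {
  cfg <- state$config
  state$iteration <- state$iteration + 1L
  state$target_records <- rbind(state$target_records, block)
  failed <- block[block$yield_percent <= state$threshold, , drop = FALSE]
  if (cfg$prune_scope == "cumulative")
    failed <- state$target_records[
      state$target_records$yield_percent <= state$threshold, , drop = FALSE]
  if (nrow(failed) > 0L)
    state$ensemble <- prune_failed(
      state$ensemble, featurize_records(failed, state$schema, state$catalog))
  train_set <- if (cfg$train_window == "cumulative") state$target_records
  else block
  mcfg <- do.call(model_config, c(
    cfg$model, list(seed = cfg$seed + state$iteration * cfg$model$n_models)))
  labeled <- label_records(train_set, state$threshold, state$catalog, state$schema)
  state$ensemble <- combine_ensembles(
    state$ensemble, train_forest_batch(labeled, mcfg, generation = state$iteration))
  if (any(block$yield_percent > state$best_so_far))
    state$best_so_far <- max(block$yield_percent)
  if (cfg$ratchet_threshold)
    state$threshold <- max(state$threshold, block$yield_percent)
  state
}

#' Rule-of-thumb iteration count
#'
#' With `n` varied reagent classes, meaningful improvements tend to appear
#' once every class but the transfer-dominant one has been examined, i.e.
#' at iteration `n - 1`.
#'
#' @param n_varied_reagent_classes integer >= 2.
#' @return recommended number of iterations, `n - 1`.
#' @export
stopping_hint <- function(n_varied_reagent_classes) {
  n <- as.integer(n_varied_reagent_classes)
  if (is.na(n) || n < 2L)
    stop("stopping_hint requires at least 2 varied reagent classes", call. = FALSE)
  n - 1L
}
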