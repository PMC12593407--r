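#' Model configuration
#'
#' Hyperparameters for one generation of forest classifiers. The defaults
#' follow the protocol: an ensemble of 100 independently seeded forests,
#' each of 10 trees grown to depth 1 ("decision stumps") so that only the
#' most transferable structure is learned.
#'
#' @param n_models number of forests per generation (ensemble members).
#' @param trees_per_model trees in each forest.
#' @param max_depth maximum tree depth (1 = stumps).
#' @param mtry features tried per split; default `floor(sqrt(p))`, at least 1.
#' @param min_leaf minimum observations per leaf.
#' @param seed base seed; member `i` of a batch trains with `seed + i`.
#' @return a `model_config` list.
#' @export
model_config <- function(n_models = 100L, trees_per_model = 10L, max_depth = 1L,
                         mtry = NULL, min_leaf = 1L, seed = 1L) {
  cfg <- list(n_models = as.integer(n_models),
              trees_per_model = as.integer(trees_per_model),
              max_depth = as.integer(max_depth),
              mtry = if (!is.null(mtry)) as.integer(mtry),
              min_leaf = as.integer(min_leaf), seed = as.integer(seed))
  with(cfg, stopifnot(n_models >= 1L, trees_per_model >= 1L, max_depth >= 1L,
                      min_leaf >= 1L, is.null(mtry) || mtry >= 1L))
  structure(cfg, class = "model_config")
}

# Grow one depth-limited CART tree on the bootstrap rows `rows`.
# Node arrays use NA feature/children for leaves; `prob` is the
# positive-class fraction of the training rows routed to the node.
grow_tree <- function(X, y, rows, max_depth, mtry, min_leaf) {
  p <- ncol(X)
  maxn <- 2L^(max_depth + 1L) - 1L
  e <- new.env(parent = emptyenv())
  e$feature <- rep(NA_integer_, maxn); e$threshold <- rep(NA_real_, maxn)
  e$left <- rep(NA_integer_, maxn); e$right <- rep(NA_integer_, maxn)
  e$prob <- rep(NA_real_, maxn); e$n <- rep(NA_integer_, maxn)
  e$k <- 0L
  build <- function(rows, depth) {
    e$k <- e$k + 1L
    id <- e$k
    pos <- mean(y[rows])
    e$prob[id] <- pos
    e$n[id] <- length(rows)
    if (depth < max_depth && pos > 0 && pos < 1 && length(rows) >= 2L * min_leaf) {
      feats <- sample.int(p, mtry)
      s <- cpp_best_split(X, y, rows, feats, min_leaf)
      if (isTRUE(s$found)) {
        e$feature[id] <- s$feature
        e$threshold[id] <- s$threshold
        goes_left <- X[rows, s$feature] <= s$threshold
        e$left[id] <- build(rows[goes_left], depth + 1L)
        e$right[id] <- build(rows[!goes_left], depth + 1L)
      }
    }
    id
  }
  build(rows, 0L)
  k <- seq_len(e$k)
  list(feature = e$feature[k], threshold = e$threshold[k], left = e$left[k],
       right = e$right[k], prob = e$prob[k], n = e$n[k])
}

new_ensemble <- function(members, width) {
  gens <- vapply(members, function(m) m$generation, integer(1))
  if (length(gens) > 1L && any(diff(gens) < 0L))
    stop("ensemble generation tags must be non-decreasing", call. = FALSE)
  if (any(vapply(members, function(m) length(m$trees), integer(1)) == 0L))
    stop("ensemble members must have at least one tree", call. = FALSE)
  structure(list(members = members, width = as.integer(width)),
            class = "atl_ensemble")
}

#' @export
print.atl_ensemble <- function(x, ...) {
  gens <- generation_tags(x)
  cat(sprintf("<atl_ensemble> %d members, %d trees, width %d; generations: %s\n",
              n_members(x), n_trees(x), x$width,
              paste(sprintf("%d x gen%d", tabulate(factor(gens)), sort(unique(gens))),
                    collapse = ", ")))
  invisible(x)
}

#' Ensemble bookkeeping helpers
#'
#' @param ensemble an `atl_ensemble`.
#' @return `n_members`/`n_trees`: integer counts; `generation_tags`: integer
#'   vector of each member's generation.
#' @export
n_members <- function(ensemble) length(ensemble$members)

#' @rdname n_members
#' @export
n_trees <- function(ensemble)
  sum(vapply(ensemble$members, function(m) length(m$trees), integer(1)))

#' @rdname n_members
#' @export
generation_tags <- function(ensemble)
  vapply(ensemble$members, function(m) m$generation, integer(1))

#' Train one generation of forest classifiers
#'
#' Trains `config$n_models` forests on the labeled set, each on its own
#' bootstrap resamples, with trees limited to `config$max_depth`. Member `i`
#' is seeded with `config$seed + i`, making the batch deterministic. A
#' single-class training set (e.g. no successes yet) yields leaf-only
#' stumps predicting the empirical positive rate.
#'
#' @param data an [label_records()] labeled set.
#' @param config a [model_config()].
#' @param generation integer generation tag for every member.
#' @return an `atl_ensemble`.
#' @export
train_forest_batch <- function(data, config, generation = 0L) {
  stopifnot(inherits(data, "atl_labeled_set"))
  X <- data$features
  y <- data$labels
  if (is.null(X) || nrow(X) == 0L) stop("cannot train on an empty set", call. = FALSE)
  storage.mode(X) <- "double"
  n <- nrow(X)
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(X))))
  mtry <- min(mtry, ncol(X))
  members <- vector("list", config$n_models)
  for (i in seq_len(config$n_models)) {
    member_seed <- config$seed + i
    set.seed(member_seed)
    trees <- vector("list", config$trees_per_model)
    for (t in seq_len(config$trees_per_model)) {
      rows <- sample.int(n, n, replace = TRUE)
      trees[[t]] <- grow_tree(X, y, rows, config$max_depth, mtry, config$min_leaf)
    }
    members[[i]] <- list(generation = as.integer(generation),
                         seed = member_seed, trees = trees)
  }
  new_ensemble(members, ncol(X))
}

check_width <- function(ensemble, X) {
  if (ncol(X) != ensemble$width)
    stop(sprintf("feature width %d does not match ensemble width %d",
                 ncol(X), ensemble$width), call. = FALSE)
}

as_feature_matrix <- function(features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  storage.mode(features) <- "double"
  features
}

#' Per-member improvement probabilities
#'
#' Each member's probability that a condition improves on the baseline:
#' the mean over its trees of the routed leaf's positive-class probability.
#'
#' @param ensemble an `atl_ensemble`.
#' @param features numeric vector (one condition) or matrix (one row per
#'   condition) of featurized conditions.
#' @return matrix, `nrow(features)` x `n_members(ensemble)`.
#' @export
predict_improvement <- function(ensemble, features) {
  X <- as_feature_matrix(features)
  check_width(ensemble, X)
  cpp_member_probs(X, ensemble$members)
}

# Per-tree routed positive probabilities plus the member index of each tree.
tree_probs <- function(ensemble, X) {
  trees <- unlist(lapply(ensemble$members, `[[`, "trees"), recursive = FALSE)
  member_of <- rep(seq_along(ensemble$members),
                   vapply(ensemble$members, function(m) length(m$trees), integer(1)))
  list(probs = cpp_tree_probs(X, trees), member_of = member_of)
}

#' Remove trees that endorsed failed conditions
#'
#' After a batch is observed, every tree that classifies any failed
#' condition as an improvement (routed leaf probability > 0.5) is removed
#' from the ensemble; members left with no trees are dropped. Pruning an
#' ensemble with no offending trees is the identity, and pruning is
#' idempotent.
#'
#' @param ensemble an `atl_ensemble`.
#' @param failed_features feature matrix of the failed conditions (observed
#'   at or below the campaign threshold), one row each.
#' @return the pruned `atl_ensemble` (possibly with zero members).
#' @export
prune_failed <- function(ensemble, failed_features) {
  if (is.null(failed_features) || NROW(failed_features) == 0L) return(ensemble)
  X <- as_feature_matrix(failed_features)
  check_width(ensemble, X)
  tp <- tree_probs(ensemble, X)
  offending <- apply(tp$probs > 0.5, 2L, any)
  if (!any(offending)) return(ensemble)
  keep_of_tree <- !offending
  members <- ensemble$members
  out <- list()
  idx <- 0L
  for (m in seq_along(members)) {
    tcount <- length(members[[m]]$trees)
    keep <- keep_of_tree[idx + seq_len(tcount)]
    idx <- idx + tcount
    if (any(keep)) {
      mem <- members[[m]]
      mem$trees <- mem$trees[keep]
      out[[length(out) + 1L]] <- mem
    }
  }
  new_ensemble(out, ensemble$width)
}

#' Merge a new generation into an ensemble
#'
#' Concatenates members, preserving order and generation tags, so that the
#' knowledge of earlier generations is retained alongside the newly trained
#' models.
#'
#' @param old,new `atl_ensemble`s of identical feature width.
#' @return the combined `atl_ensemble`.
#' @export
combine_ensembles <- function(old, new) {
  if (old$width != new$width)
    stop(sprintf("cannot combine ensembles of widths %d and %d",
                 old$width, new$width), call. = FALSE)
  structure(list(members = c(old$members, new$members), width = old$width),
            class = "atl_ensemble")
}

empty_ensemble <- function(width)
  structure(list(members = list(), width = as.integer(width)),
            class = "atl_ensemble")

#' Reagent-class usage of an ensemble's split features
#'
#' Counts every split node's feature, maps it to a reagent class through the
#' schema, and normalizes to fractions summing to 1. With depth-1 trees this
#' is exactly the distribution of root-split classes, the quantity used to
#' follow what each generation of models has learned. Leaf-only stumps
#' contribute nothing.
#'
#' @param ensemble an `atl_ensemble` trained on features laid out by `schema`.
#' @param schema the [build_schema()] schema.
#' @param by_generation if `TRUE`, return one row of fractions per
#'   generation present in the ensemble.
#' @return named numeric vector over classes (substrate, ligand, solvent,
#'   precatalyst, additive), or a matrix with one such row per generation.
#'   All-zero when the ensemble has no split nodes; attribute `n_splits`
#'   carries the split count(s).
#' @export
descriptor_usage <- function(ensemble, schema, by_generation = FALSE) {
  if (ensemble$width != schema$width)
    stop("ensemble width does not match schema width", call. = FALSE)
  split_class <- function(members) {
    feats <- unlist(lapply(members, function(m)
      unlist(lapply(m$trees, function(tr) tr$feature[!is.na(tr$feature)]))))
    counts <- table(factor(schema$class_of_feature[feats], levels = FEATURE_CLASSES))
    counts <- as.numeric(counts)
    names(counts) <- FEATURE_CLASSES
    counts
  }
  if (!by_generation) {
    counts <- split_class(ensemble$members)
    tot <- sum(counts)
    out <- if (tot > 0) counts / tot else counts
    attr(out, "n_splits") <- tot
    return(out)
  }
  gens <- generation_tags(ensemble)
  ug <- sort(unique(gens))
  out <- matrix(0, length(ug), length(FEATURE_CLASSES),
                dimnames = list(paste0("gen", ug), FEATURE_CLASSES))
  nsplits <- setNames(numeric(length(ug)), rownames(out))
  for (i in seq_along(ug)) {
    counts <- split_class(ensemble$members[gens == ug[i]])
    tot <- sum(counts)
    out[i, ] <- if (tot > 0) counts / tot else counts
    nsplits[i] <- tot
  }
  attr(out, "n_splits") <- nsplits
  out
}

#' Serialize / restore an ensemble
#'
#' Versioned JSON holding every tree's split features, thresholds, children,
#' leaf probabilities, plus generation tags and training seeds. Leaves are
#' encoded with feature/children = -1.
#'
#' @param ensemble an `atl_ensemble`.
#' @param path JSON file path.
#' @return `write_ensemble`: `path`, invisibly. `read_ensemble`: the
#'   restored `atl_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  enc_tree <- function(tr) {
    list(feature = ifelse(is.na(tr$feature), -1L, tr$feature),
         threshold = ifelse(is.na(tr$threshold), 0, tr$threshold),
         left = ifelse(is.na(tr$left), -1L, tr$left),
         right = ifelse(is.na(tr$right), -1L, tr$right),
         prob = tr$prob, n = tr$n)
  }
  obj <- list(format = "atlrxn-ensemble", version = 1L, width = ensemble$width,
              members = lapply(ensemble$members, function(m)
                list(generation = m$generation, seed = m$seed,
                     trees = lapply(m$trees, enc_tree))))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "atlrxn-ensemble"))
    stop("not an atlrxn ensemble file: ", path, call. = FALSE)
  dec_tree <- function(tr) {
    f <- as.integer(tr$feature)
    list(feature = ifelse(f < 0L, NA_integer_, f),
         threshold = ifelse(f < 0L, NA_real_, as.numeric(tr$threshold)),
         left = ifelse(as.integer(tr$left) < 0L, NA_integer_, as.integer(tr$left)),
         right = ifelse(as.integer(tr$right) < 0L, NA_integer_, as.integer(tr$right)),
         prob = as.numeric(tr$prob), n = as.integer(tr$n))
  }
  members <- lapply(obj$members, function(m)
    list(generation = as.integer(m$generation), seed = as.integer(m$seed),
         trees = lapply(m$trees, dec_tree)))
  new_ensemble(members, as.integer(obj$width))
}
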