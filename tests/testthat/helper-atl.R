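# Shared fixtures: all built in code, sized for speed.

tiny_catalog <- function(np = 2, nl = 3, nad = 3, ns = 2,
                         lig_d = 2, sol_d = 2, sub_d = 1, seed = 42) {
  set.seed(seed)
  mk_desc <- function(n, d) {
    m <- matrix(round(rnorm(n * d), 4), n, d)
    colnames(m) <- paste0("d", seq_len(d))
    as.data.frame(m)
  }
  additives <- data.frame(
    id = c("none", paste0("Ad", seq_len(nad - 1))),
    cation = c("none", paste0("Cat", seq_len(nad - 1))),
    anion = c("none", rep(c("X", "Y"), length.out = nad - 1)))[seq_len(nad), ]
  reagent_catalog(
    precatalysts = paste0("P", seq_len(np)),
    ligands = cbind(data.frame(id = paste0("L", seq_len(nl))), mk_desc(nl, lig_d)),
    additives = additives,
    solvents = cbind(data.frame(id = paste0("S", seq_len(ns))), mk_desc(ns, sol_d)),
    substrates = cbind(data.frame(id = c("am1", "am2", "ac1", "ac2"),
                                  role = c("amine", "amine", "acid", "acid")),
                       mk_desc(4, sub_d)))
}

tiny_pair <- function(catalog = tiny_catalog()) c("am1", "ac1")

# Hand-built trees in the internal node-array representation.
make_stump <- function(feature, threshold, p_left, p_right) {
  list(feature = c(as.integer(feature), NA_integer_, NA_integer_),
       threshold = c(threshold, NA_real_, NA_real_),
       left = c(2L, NA_integer_, NA_integer_),
       right = c(3L, NA_integer_, NA_integer_),
       prob = c((p_left + p_right) / 2, p_left, p_right),
       n = c(2L, 1L, 1L))
}

make_leaf <- function(p) {
  list(feature = NA_integer_, threshold = NA_real_, left = NA_integer_,
       right = NA_integer_, prob = p, n = 1L)
}

manual_ensemble <- function(tree_sets, width, generations = NULL) {
  generations <- generations %||% rep(0L, length(tree_sets))
  members <- Map(function(trees, g)
    list(generation = as.integer(g), seed = 0L, trees = trees),
    tree_sets, generations)
  atlrxn:::new_ensemble(unname(members), width)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A labeled set straight from matrices (bypasses record plumbing).
raw_labeled_set <- function(X, y, threshold = 50) {
  structure(list(features = X, labels = as.integer(y),
                 threshold_percent = threshold),
            class = "atl_labeled_set")
}

# Random records over a catalog, uniform conditions and yields.
random_records <- function(catalog, n, pair = c("am1", "ac1"),
                           domain = "source", iteration = 0L, seed = 1) {
  set.seed(seed)
  pick <- function(ids) ids[sample.int(length(ids), n, replace = TRUE)]
  data.frame(amine_id = pair[1], acid_id = pair[2],
             precatalyst = pick(catalog$precatalysts),
             ligand = pick(catalog$ligands$id),
             additive = pick(catalog$additives$id),
             solvent = pick(catalog$solvents$id),
             yield_percent = round(runif(n, 0, 100), 2),
             domain = domain, iteration = iteration,
             stringsAsFactors = FALSE)
}
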