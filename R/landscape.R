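#' Construct a yield landscape explicitly
#'
#' A landscape is a ground-truth map from a condition (precatalyst, ligand,
#' additive, solvent) to an assay yield in percent: base yield plus one main
#' effect per reagent, plus sparse pairwise cross-class interactions, plus
#' optional Gaussian noise, clipped to \[0, 100\]. Effects not listed default
#' to 0.
#'
#' @param catalog a [reagent_catalog()]; effect names must resolve in it.
#' @param effects named list over `precatalyst`, `ligand`, `additive`,
#'   `solvent`: each a named numeric vector of main effects (percent).
#' @param base base yield in percent.
#' @param interactions NULL or data.frame with columns `class1`, `id1`,
#'   `class2`, `id2`, `effect`.
#' @param noise_sd Gaussian noise standard deviation (percent), applied
#'   before clipping when evaluation is noisy.
#' @param substrate_pair (amine id, acid id) the landscape describes.
#' @return an `atl_landscape`.
#' @export
make_landscape <- function(catalog, effects = list(), base = 20,
                           interactions = NULL, noise_sd = 0,
                           substrate_pair = NULL) {
  eff <- lapply(setNames(REAGENT_CLASSES, REAGENT_CLASSES), function(cls) {
    ids <- catalog_ids(catalog, cls)
    e <- setNames(numeric(length(ids)), ids)
    given <- effects[[cls]]
    if (!is.null(given)) {
      resolve_or_stop(names(given), ids, cls)
      e[names(given)] <- given
    }
    e
  })
  if (!is.null(interactions)) {
    interactions <- as.data.frame(interactions)
    stopifnot(all(c("class1", "id1", "class2", "id2", "effect") %in%
                    names(interactions)))
    for (i in seq_len(nrow(interactions))) {
      resolve_or_stop(interactions$id1[i],
                      catalog_ids(catalog, interactions$class1[i]),
                      interactions$class1[i])
      resolve_or_stop(interactions$id2[i],
                      catalog_ids(catalog, interactions$class2[i]),
                      interactions$class2[i])
    }
  }
  if (is.null(substrate_pair)) {
    su <- catalog$substrates
    substrate_pair <- c(su$id[su$role == "amine"][1], su$id[su$role == "acid"][1])
  }
  structure(list(base = as.numeric(base), effects = eff,
                 interactions = interactions, noise_sd = as.numeric(noise_sd),
                 substrate_pair = as.character(substrate_pair)),
            class = "atl_landscape")
}

#' Default landscape-pair specification
#'
#' The stated synthetic world: ligand is the dominant reagent class (largest
#' main-effect scale), ligand/solvent effects are tied to their catalog
#' descriptors (fraction `rho_descriptor` of effect variance explained by a
#' random linear map of the descriptors), additive effects decompose into
#' independent cation and anion contributions, 5% of cross-class reagent
#' pairs carry interactions at half the main-effect scale, and observation
#' noise is 5 percentage points. `divergence` in \[0, 1\] sets how far
#' non-shared-class effects of the source landscape are decorrelated from
#' the target's (corr = 1 - divergence); `shared_classes` (default ligand)
#' are copied exactly.
#'
#' @param base base yield, percent.
#' @param scales named effect scales (sd, percent) for ligand, solvent,
#'   precatalyst, cation, anion.
#' @param rho_descriptor fraction of ligand/solvent effect variance carried
#'   by descriptors.
#' @param interaction_density fraction of cross-class id pairs with an
#'   interaction term.
#' @param interaction_scale_frac interaction sd as a fraction of the mean
#'   main-effect scale.
#' @param noise_sd observation noise sd, percent.
#' @param shared_classes classes whose main effects are identical in source
#'   and target.
#' @param divergence decorrelation of non-shared effects, in \[0, 1\].
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(base = 20,
                           scales = c(ligand = 15, solvent = 6, precatalyst = 5,
                                      cation = 4, anion = 4),
                           rho_descriptor = 0.8, interaction_density = 0.05,
                           interaction_scale_frac = 0.5, noise_sd = 5,
                           shared_classes = "ligand", divergence = 1) {
  spec <- list(base = as.numeric(base), scales = unlist(scales),
               rho_descriptor = as.numeric(rho_descriptor),
               interaction_density = as.numeric(interaction_density),
               interaction_scale_frac = as.numeric(interaction_scale_frac),
               noise_sd = as.numeric(noise_sd),
               shared_classes = as.character(shared_classes),
               divergence = as.numeric(divergence))
  need <- c("ligand", "solvent", "precatalyst", "cation", "anion")
  if (!all(need %in% names(spec$scales)) || any(spec$scales[need] < 0))
    stop("landscape spec: scales must name non-negative ",
         paste(need, collapse = ", "), call. = FALSE)
  if (spec$divergence < 0 || spec$divergence > 1)
    stop("landscape spec: divergence must be in [0, 1]", call. = FALSE)
  if (spec$rho_descriptor < 0 || spec$rho_descriptor > 1)
    stop("landscape spec: rho_descriptor must be in [0, 1]", call. = FALSE)
  if (spec$interaction_density < 0 || spec$interaction_density > 1)
    stop("landscape spec: interaction_density must be in [0, 1]", call. = FALSE)
  if (spec$noise_sd < 0)
    stop("landscape spec: noise_sd must be non-negative", call. = FALSE)
  if (!all(spec$shared_classes %in% REAGENT_CLASSES))
    stop("landscape spec: unknown shared class", call. = FALSE)
  structure(spec, class = "landscape_spec")
}

# Standardize to unit variance (guarding degenerate vectors).
unit_z <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s < 1e-12) return(rep(0, length(v)))
  (v - mean(v)) / s
}

# Main effects for a descriptor class: rho of the variance from a random
# linear map of the descriptors, the rest idiosyncratic.
draw_desc_effects <- function(desc, scale, rho) {
  n <- nrow(desc)
  idio <- unit_z(rnorm(n))
  if (ncol(desc) == 0L || rho == 0) {
    e <- scale * idio
  } else {
    z <- unit_z(as.numeric(desc %*% rnorm(ncol(desc))))
    e <- scale * (sqrt(rho) * z + sqrt(1 - rho) * idio)
  }
  setNames(e, rownames(desc))
}

draw_additive_effects <- function(additives, cation_scale, anion_scale) {
  cations <- unique(additives$cation[additives$cation != "none"])
  anions <- unique(additives$anion[additives$anion != "none"])
  ce <- setNames(rnorm(length(cations), 0, cation_scale), cations)
  ae <- setNames(rnorm(length(anions), 0, anion_scale), anions)
  e <- ifelse(additives$cation == "none", 0, ce[additives$cation]) +
    ifelse(additives$anion == "none", 0, ae[additives$anion])
  setNames(as.numeric(e), additives$id)
}

draw_interactions <- function(catalog, spec) {
  pairs <- utils::combn(REAGENT_CLASSES, 2)
  rows <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g <- expand.grid(id1 = catalog_ids(catalog, pairs[1, k]),
                     id2 = catalog_ids(catalog, pairs[2, k]),
                     stringsAsFactors = FALSE)
    cbind(class1 = pairs[1, k], g["id1"], class2 = pairs[2, k], g["id2"])
  }))
  m <- floor(spec$interaction_density * nrow(rows))
  if (m == 0L) return(NULL)
  sel <- sort(sample.int(nrow(rows), m))
  out <- rows[sel, , drop = FALSE]
  sc <- mean(spec$scales[c("ligand", "solvent", "precatalyst", "cation", "anion")])
  out$effect <- rnorm(m, 0, spec$interaction_scale_frac * sc)
  rownames(out) <- NULL
  out
}

#' Generate a source/target landscape pair
#'
#' Draws the target landscape first, then derives the source landscape from
#' it: main effects of `shared_classes` (default: ligand) are copied
#' exactly; effects of the other classes (and interaction values) are
#' variance-preserving mixtures with fresh draws so that their correlation
#' with the target is `1 - divergence`. Deterministic for a fixed seed.
#'
#' @param catalog a [reagent_catalog()].
#' @param spec a [landscape_spec()].
#' @param seed integer seed.
#' @param target_pair,source_pair (amine id, acid id) for each domain;
#'   defaults: first amine/acid in the catalog for the target, second
#'   (when available) for the source.
#' @return an `atl_landscape_pair`: list with `source`, `target`, `spec`,
#'   `seed`.
#' @export
make_landscape_pair <- function(catalog, spec = landscape_spec(), seed = 1L,
                                target_pair = NULL, source_pair = NULL) {
  if (!inherits(spec, "landscape_spec")) spec <- do.call(landscape_spec, spec)
  su <- catalog$substrates
  amines <- su$id[su$role == "amine"]
  acids <- su$id[su$role == "acid"]
  target_pair <- target_pair %||% c(amines[1], acids[1])
  source_pair <- source_pair %||% c(amines[min(2L, length(amines))],
                                    acids[min(2L, length(acids))])
  set.seed(as.integer(seed))
  tgt_eff <- list(
    precatalyst = setNames(rnorm(length(catalog$precatalysts), 0,
                                 spec$scales[["precatalyst"]]),
                           catalog$precatalysts),
    ligand = draw_desc_effects(desc_matrix(catalog$ligands),
                               spec$scales[["ligand"]], spec$rho_descriptor),
    additive = draw_additive_effects(catalog$additives, spec$scales[["cation"]],
                                     spec$scales[["anion"]]),
    solvent = draw_desc_effects(desc_matrix(catalog$solvents),
                                spec$scales[["solvent"]], spec$rho_descriptor))
  tgt_int <- draw_interactions(catalog, spec)

  a <- 1 - spec$divergence
  b <- sqrt(max(0, 1 - a^2))
  mix <- function(target, fresh) a * target + b * fresh
  src_eff <- tgt_eff
  for (cls in setdiff(REAGENT_CLASSES, spec$shared_classes)) {
    fresh <- switch(cls,
                    precatalyst = setNames(rnorm(length(tgt_eff$precatalyst), 0,
                                                 spec$scales[["precatalyst"]]),
                                           names(tgt_eff$precatalyst)),
                    ligand = draw_desc_effects(desc_matrix(catalog$ligands),
                                               spec$scales[["ligand"]],
                                               spec$rho_descriptor),
                    additive = draw_additive_effects(
                      catalog$additives, spec$scales[["cation"]],
                      spec$scales[["anion"]]),
                    solvent = draw_desc_effects(desc_matrix(catalog$solvents),
                                                spec$scales[["solvent"]],
                                                spec$rho_descriptor))
    src_eff[[cls]] <- mix(tgt_eff[[cls]], fresh)
  }
  src_int <- tgt_int
  if (!is.null(tgt_int)) {
    sc <- mean(spec$scales[c("ligand", "solvent", "precatalyst", "cation", "anion")])
    src_int$effect <- mix(tgt_int$effect,
                          rnorm(nrow(tgt_int), 0,
                                spec$interaction_scale_frac * sc))
  }
  mk <- function(eff, int, pair)
    make_landscape(catalog, effects = eff, base = spec$base, interactions = int,
                   noise_sd = spec$noise_sd, substrate_pair = pair)
  structure(list(source = mk(src_eff, src_int, source_pair),
                 target = mk(tgt_eff, tgt_int, target_pair),
                 spec = spec, seed = as.integer(seed)),
            class = "atl_landscape_pair")
}

#' Evaluate a landscape
#'
#' Vectorized ground-truth yield for conditions: base + main effects +
#' matching interactions (+ Gaussian noise when `noisy`), clipped to
#' \[0, 100\]. Noise uses the current R random stream. Noiseless evaluation
#' is pure.
#'
#' @param landscape an `atl_landscape`.
#' @param conditions data.frame of conditions (or a single named
#'   list/vector).
#' @param noisy add `landscape$noise_sd` Gaussian noise before clipping.
#' @return numeric yields, percent.
#' @export
eval_yield <- function(landscape, conditions, noisy = FALSE) {
  if (!is.data.frame(conditions))
    conditions <- as.data.frame(as.list(conditions), stringsAsFactors = FALSE)
  y <- rep(landscape$base, nrow(conditions))
  for (cls in REAGENT_CLASSES) {
    e <- landscape$effects[[cls]]
    hit <- match(conditions[[cls]], names(e))
    if (anyNA(hit))
      stop(sprintf("unknown %s identifier(s): %s", cls,
                   paste(unique(conditions[[cls]][is.na(hit)]), collapse = ", ")),
           call. = FALSE)
    y <- y + e[hit]
  }
  int <- landscape$interactions
  if (!is.null(int) && nrow(int) > 0L)
    for (i in seq_len(nrow(int))) {
      hit <- conditions[[int$class1[i]]] == int$id1[i] &
        conditions[[int$class2[i]]] == int$id2[i]
      y[hit] <- y[hit] + int$effect[i]
    }
  if (noisy && landscape$noise_sd > 0)
    y <- y + rnorm(length(y), 0, landscape$noise_sd)
  unname(pmin(100, pmax(0, y)))
}

#' Yield oracle from a landscape
#'
#' @param landscape an `atl_landscape`.
#' @param noisy observe with noise (default) or noiselessly.
#' @return function mapping a data.frame of conditions to observed yields;
#'   suitable for [run_iteration()] / [run_campaign()].
#' @export
make_oracle <- function(landscape, noisy = TRUE)
  function(conditions) eval_yield(landscape, conditions, noisy = noisy)

#' Draw a synthetic source dataset from a landscape
#'
#' Emulates the pre-campaign source reactions: `n` distinct conditions
#' sampled from the space with an optional bias toward one reagent (by
#' default 80% of draws use the source landscape's best ligand, mirroring a
#' source dataset dominated by its most successful ligand), observed with
#' noise and tagged `domain = "source"`, `iteration = 0`.
#'
#' @param landscape the source `atl_landscape`.
#' @param catalog the catalog the landscape was built on.
#' @param sampling list: `n` (default 72), `bias_class` (default
#'   `"ligand"`), `bias_id` (default: identifier with the largest main
#'   effect in `bias_class`), `bias_prob` (default 0.8).
#' @param seed integer seed.
#' @return a [reaction_records()] data.frame with `n` rows.
#' @export
source_dataset_from_landscape <- function(landscape, catalog,
                                          sampling = list(), seed = 1L) {
  smp <- modifyList(list(n = 72L, bias_class = "ligand", bias_id = NULL,
                         bias_prob = 0.8), sampling)
  n <- as.integer(smp$n)
  space_size <- prod(catalog_sizes(catalog))
  if (n > space_size)
    stop(sprintf("requested %d source reactions but the space has only %d conditions",
                 n, space_size), call. = FALSE)
  stopifnot(smp$bias_class %in% REAGENT_CLASSES,
            smp$bias_prob >= 0, smp$bias_prob <= 1)
  bias_id <- smp$bias_id %||%
    names(which.max(landscape$effects[[smp$bias_class]]))
  set.seed(as.integer(seed))
  draw1 <- function() {
    cond <- lapply(setNames(REAGENT_CLASSES, REAGENT_CLASSES), function(cls) {
      ids <- catalog_ids(catalog, cls)
      if (cls == smp$bias_class && runif(1) < smp$bias_prob) bias_id
      else ids[sample.int(length(ids), 1L)]
    })
    as.data.frame(cond, stringsAsFactors = FALSE)
  }
  seen <- character(0)
  conds <- vector("list", n)
  k <- 0L
  while (k < n) {
    cond <- draw1()
    key <- cond_key(cond)
    if (key %in% seen) next
    k <- k + 1L
    seen <- c(seen, key)
    conds[[k]] <- cond
  }
  conds <- do.call(rbind, conds)
  yields <- eval_yield(landscape, conds, noisy = TRUE)
  reaction_records(cbind(
    data.frame(amine_id = landscape$substrate_pair[1],
               acid_id = landscape$substrate_pair[2],
               stringsAsFactors = FALSE),
    conds,
    data.frame(yield_percent = yields, domain = "source", iteration = 0L,
               stringsAsFactors = FALSE)))
}

#' Serialize / restore landscapes
#'
#' JSON representation for exact replay of a landscape or landscape pair.
#'
#' @param x an `atl_landscape` or `atl_landscape_pair`.
#' @param path JSON file path.
#' @return `write_landscape`: `path`, invisibly. `read_landscape`: the
#'   restored object.
#' @export
write_landscape <- function(x, path) {
  enc <- function(l) list(base = l$base, effects = lapply(l$effects, as.list),
                          interactions = l$interactions, noise_sd = l$noise_sd,
                          substrate_pair = l$substrate_pair)
  obj <- if (inherits(x, "atl_landscape_pair"))
    list(format = "atlrxn-landscape-pair", version = 1L,
         source = enc(x$source), target = enc(x$target),
         spec = modifyList(unclass(x$spec),
                           list(scales = as.list(x$spec$scales))),
         seed = x$seed)
  else list(format = "atlrxn-landscape", version = 1L, landscape = enc(x))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(l) structure(
    list(base = as.numeric(l$base), effects = lapply(l$effects, unlist),
         interactions = if (!is.null(l$interactions) && NROW(l$interactions))
           as.data.frame(l$interactions),
         noise_sd = as.numeric(l$noise_sd),
         substrate_pair = as.character(l$substrate_pair)),
    class = "atl_landscape")
  if (identical(obj$format, "atlrxn-landscape-pair"))
    structure(list(source = dec(obj$source), target = dec(obj$target),
                   spec = do.call(landscape_spec, obj$spec),
                   seed = as.integer(obj$seed)),
              class = "atl_landscape_pair")
  else if (identical(obj$format, "atlrxn-landscape")) dec(obj$landscape)
  else stop("not an atlrxn landscape file: ", path, call. = FALSE)
}
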