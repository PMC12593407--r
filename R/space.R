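#' Enumerate the combinatorial condition space
#'
#' Full Cartesian product of the catalog's four reagent classes, in
#' lexicographic order by catalog position of (precatalyst, ligand, additive,
#' solvent) — the first class varies slowest. Classes named in `fixed` are
#' pinned to a single identifier instead of being varied.
#'
#' @param catalog a [reagent_catalog()].
#' @param fixed optional named list/vector pinning some of `precatalyst`,
#'   `ligand`, `additive`, `solvent` to one identifier each.
#' @return data.frame with columns `precatalyst`, `ligand`, `additive`,
#'   `solvent`; one row per condition.
#' @examples
#' cond <- enumerate_space(example_catalog())
#' nrow(cond)  # 5 * 29 * 14 * 9 = 18270
#' @export
enumerate_space <- function(catalog, fixed = NULL) {
  pools <- list(precatalyst = catalog$precatalysts,
                ligand = catalog$ligands$id,
                additive = catalog$additives$id,
                solvent = catalog$solvents$id)
  if (!is.null(fixed)) {
    fixed <- as.list(fixed)
    bad <- setdiff(names(fixed), REAGENT_CLASSES)
    if (length(bad))
      stop("fixed names unknown reagent class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (cls in names(fixed)) {
      resolve_or_stop(fixed[[cls]], pools[[cls]], cls)
      pools[[cls]] <- as.character(fixed[[cls]])
    }
  }
  # expand.grid varies the first factor fastest; feed classes reversed so
  # precatalyst varies slowest, then restore column order.
  g <- expand.grid(rev(pools), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, REAGENT_CLASSES]
  rownames(g) <- NULL
  g
}

#' Build the featurization schema for a campaign
#'
#' Fixes the block layout used to turn a condition into a numeric vector:
#' amine-substrate descriptors, acid-substrate descriptors, ligand
#' descriptors, solvent descriptors, then one-hot blocks for precatalyst,
#' additive cation and additive anion. The cation/anion levels are derived
#' from the additive list; the `"none"` additive encodes as all-zero ion
#' blocks. Every feature index is mapped to a reagent class (substrate,
#' ligand, solvent, precatalyst, additive) for downstream attribution.
#'
#' @param catalog a [reagent_catalog()].
#' @param substrate_pair character of length 2: (amine-derived id,
#'   acid-derived id), both present in the catalog with matching roles.
#' @return an object of class `atl_schema` with elements `blocks` (named
#'   widths), `feature_names`, `class_of_feature`, `width`, one-hot level
#'   vectors and the substrate pair.
#' @export
build_schema <- function(catalog, substrate_pair) {
  stopifnot(length(substrate_pair) == 2L)
  substrate_pair <- as.character(substrate_pair)
  resolve_or_stop(substrate_pair, catalog$substrates$id, "substrate")
  roles <- catalog$substrates$role[match(substrate_pair, catalog$substrates$id)]
  if (!identical(roles, c("amine", "acid")))
    stop("substrate_pair must be (amine-derived, acid-derived); got roles: ",
         paste(roles, collapse = ", "), call. = FALSE)

  sub_d <- ncol(desc_matrix(catalog$substrates, skip = c("id", "role")))
  lig_d <- ncol(desc_matrix(catalog$ligands))
  sol_d <- ncol(desc_matrix(catalog$solvents))
  cations <- ion_levels(catalog, "cation")
  anions <- ion_levels(catalog, "anion")

  blocks <- c(amine_substrate = sub_d, acid_substrate = sub_d,
              ligand = lig_d, solvent = sol_d,
              precatalyst = length(catalog$precatalysts),
              cation = length(cations), anion = length(anions))
  block_class <- c(amine_substrate = "substrate", acid_substrate = "substrate",
                   ligand = "ligand", solvent = "solvent",
                   precatalyst = "precatalyst", cation = "additive",
                   anion = "additive")
  nm <- function(prefix, x) if (length(x)) paste0(prefix, ".", x) else character(0)
  feature_names <- c(
    nm("amine", colnames(desc_matrix(catalog$substrates, c("id", "role")))),
    nm("acid", colnames(desc_matrix(catalog$substrates, c("id", "role")))),
    nm("ligand", colnames(desc_matrix(catalog$ligands))),
    nm("solvent", colnames(desc_matrix(catalog$solvents))),
    nm("precatalyst", catalog$precatalysts),
    nm("cation", cations), nm("anion", anions))
  structure(list(blocks = blocks,
                 class_of_feature = rep(unname(block_class[names(blocks)]), blocks),
                 feature_names = feature_names,
                 width = sum(blocks),
                 precatalyst_levels = catalog$precatalysts,
                 cation_levels = cations, anion_levels = anions,
                 substrate_pair = substrate_pair),
            class = "atl_schema")
}

#' @export
print.atl_schema <- function(x, ...) {
  cat(sprintf("<atl_schema> width %d; blocks: %s; substrates %s + %s\n",
              x$width, paste(sprintf("%s[%d]", names(x$blocks), x$blocks),
                             collapse = " "),
              x$substrate_pair[1], x$substrate_pair[2]))
  invisible(x)
}

one_hot <- function(ids, levels) {
  m <- matrix(0, length(ids), length(levels))
  hit <- match(ids, levels)                      # NA for "none": row stays 0
  ok <- which(!is.na(hit))
  m[cbind(ok, hit[ok])] <- 1
  m
}

#' Featurize conditions
#'
#' Maps conditions to fixed-length numeric vectors under a schema:
#' continuous descriptor blocks are copied from the catalog tables, one-hot
#' blocks mark the precatalyst and the additive's cation and anion
#' independently. The designated `"none"` additive yields all-zero ion
#' blocks.
#'
#' @param conditions data.frame of conditions (columns `precatalyst`,
#'   `ligand`, `additive`, `solvent`); a single condition may be given as a
#'   named list/vector.
#' @param substrate_pair (amine id, acid id), must equal the schema's pair.
#' @param schema an [build_schema()] result.
#' @param catalog the catalog the schema was built from.
#' @return numeric matrix, one row per condition, `schema$width` columns.
#' @export
featurize <- function(conditions, substrate_pair, schema, catalog) {
  if (!is.data.frame(conditions))
    conditions <- as.data.frame(as.list(conditions), stringsAsFactors = FALSE)
  substrate_pair <- as.character(substrate_pair)
  if (!identical(substrate_pair, schema$substrate_pair))
    stop("substrate_pair does not match the schema's campaign pair", call. = FALSE)
  for (cls in REAGENT_CLASSES)
    resolve_or_stop(conditions[[cls]], catalog_ids(catalog, cls), cls)
  n <- nrow(conditions)

  sub_m <- desc_matrix(catalog$substrates, skip = c("id", "role"))
  amine <- sub_m[rep(match(substrate_pair[1], rownames(sub_m)), n), , drop = FALSE]
  acid <- sub_m[rep(match(substrate_pair[2], rownames(sub_m)), n), , drop = FALSE]
  lig_m <- desc_matrix(catalog$ligands)
  sol_m <- desc_matrix(catalog$solvents)
  ad <- catalog$additives
  ai <- match(conditions$additive, ad$id)

  X <- cbind(amine, acid,
             lig_m[match(conditions$ligand, rownames(lig_m)), , drop = FALSE],
             sol_m[match(conditions$solvent, rownames(sol_m)), , drop = FALSE],
             one_hot(conditions$precatalyst, schema$precatalyst_levels),
             one_hot(ad$cation[ai], schema$cation_levels),
             one_hot(ad$anion[ai], schema$anion_levels))
  dimnames(X) <- list(NULL, schema$feature_names)
  X
}
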