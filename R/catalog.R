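#' Reagent catalog
#'
#' A reagent catalog holds the inventories of the four varied reagent classes
#' (precatalysts, ligands, additives, solvents) plus the substrate inventory.
#' Ligands, solvents and substrates carry continuous physical-descriptor
#' columns; additives are decomposed into a cation and an anion identifier so
#' that models can generalize across salts sharing an ion. A designated
#' `"none"` additive (cation and anion both `"none"`) encodes the
#' additive-free control.
#'
#' @param precatalysts character vector of precatalyst identifiers.
#' @param ligands data.frame: column `id` then numeric descriptor columns.
#' @param additives data.frame with columns `id`, `cation`, `anion`.
#' @param solvents data.frame: column `id` then numeric descriptor columns.
#' @param substrates data.frame: columns `id`, `role` (one of `"amine"`,
#'   `"acid"`) then numeric descriptor columns.
#' @return an object of class `reagent_catalog`.
#' @export
reagent_catalog <- function(precatalysts, ligands, additives, solvents, substrates) {
  precatalysts <- as.character(precatalysts)
  cat <- structure(
    list(precatalysts = precatalysts,
         ligands = as.data.frame(ligands),
         additives = as.data.frame(additives),
         solvents = as.data.frame(solvents),
         substrates = as.data.frame(substrates)),
    class = "reagent_catalog")
  validate_catalog(cat)
}

validate_catalog <- function(cat, where = "catalog") {
  chk_unique <- function(ids, class) {
    if (anyDuplicated(ids))
      stop(sprintf("%s: duplicate %s identifier(s): %s", where, class,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           call. = FALSE)
    if (length(ids) == 0L)
      stop(sprintf("%s: empty %s inventory", where, class), call. = FALSE)
    if (any(is.na(ids) | ids == ""))
      stop(sprintf("%s: missing %s identifier", where, class), call. = FALSE)
  }
  chk_desc <- function(df, class, skip = "id") {
    dcols <- setdiff(names(df), skip)
    for (cl in dcols)
      if (!is.numeric(df[[cl]]))
        stop(sprintf("%s: non-numeric descriptor column '%s' in %s table",
                     where, cl, class), call. = FALSE)
  }
  chk_unique(cat$precatalysts, "precatalyst")
  for (class in c("ligands", "solvents")) {
    df <- cat[[class]]
    if (!"id" %in% names(df))
      stop(sprintf("%s: %s table lacks an 'id' column", where, class), call. = FALSE)
    df$id <- as.character(df$id)
    chk_unique(df$id, sub("s$", "", class))
    chk_desc(df, class)
    cat[[class]] <- df
  }
  ad <- cat$additives
  if (!all(c("id", "cation", "anion") %in% names(ad)))
    stop(sprintf("%s: additive table needs columns id, cation, anion", where),
         call. = FALSE)
  ad[] <- lapply(ad, as.character)
  chk_unique(ad$id, "additive")
  cat$additives <- ad
  su <- cat$substrates
  if (!all(c("id", "role") %in% names(su)))
    stop(sprintf("%s: substrate table needs columns id, role", where), call. = FALSE)
  su$id <- as.character(su$id)
  su$role <- as.character(su$role)
  chk_unique(su$id, "substrate")
  if (!all(su$role %in% c("amine", "acid")))
    stop(sprintf("%s: substrate role must be 'amine' or 'acid'", where), call. = FALSE)
  chk_desc(su, "substrates", skip = c("id", "role"))
  cat$substrates <- su
  cat
}

#' @export
print.reagent_catalog <- function(x, ...) {
  sz <- catalog_sizes(x)
  cat("<reagent_catalog> ", paste(sprintf("%d %ss", sz, names(sz)), collapse = ", "),
      sprintf("; %d substrates (%d amine / %d acid)\n", nrow(x$substrates),
              sum(x$substrates$role == "amine"), sum(x$substrates$role == "acid")),
      sep = "")
  invisible(x)
}

#' Class sizes of a catalog
#'
#' @param catalog a [reagent_catalog()].
#' @return named integer vector over precatalyst, ligand, additive, solvent.
#' @export
catalog_sizes <- function(catalog) {
  c(precatalyst = length(catalog$precatalysts),
    ligand = nrow(catalog$ligands),
    additive = nrow(catalog$additives),
    solvent = nrow(catalog$solvents))
}

catalog_ids <- function(catalog, class) {
  switch(class,
         precatalyst = catalog$precatalysts,
         ligand = catalog$ligands$id,
         additive = catalog$additives$id,
         solvent = catalog$solvents$id,
         substrate = catalog$substrates$id,
         stop("unknown reagent class: ", class, call. = FALSE))
}

# Cation/anion levels are derived from the listed additives; the designated
# "none" value is not a level (it encodes an all-zero one-hot block).
ion_levels <- function(catalog, which = c("cation", "anion")) {
  which <- match.arg(which)
  v <- catalog$additives[[which]]
  unique(v[v != "none"])
}

desc_matrix <- function(df, skip = "id") {
  dcols <- setdiff(names(df), skip)
  m <- as.matrix(df[, dcols, drop = FALSE])
  rownames(m) <- df$id
  m
}

resolve_or_stop <- function(ids, pool, class) {
  bad <- setdiff(unique(ids), pool)
  if (length(bad))
    stop(sprintf("unknown %s identifier(s): %s", class, paste(bad, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a reagent catalog from CSV files
#'
#' Expects one file per table. `path` may be a directory containing
#' `precatalysts.csv`, `ligands.csv`, `additives.csv`, `solvents.csv`,
#' `substrates.csv`, or a named character vector/list with those five names
#' (without extension) mapping to file paths.
#'
#' @param path directory or named vector of file paths.
#' @return a validated [reagent_catalog()].
#' @export
read_catalog <- function(path) {
  tables <- c("precatalysts", "ligands", "additives", "solvents", "substrates")
  if (is.character(path) && length(path) == 1L && dir.exists(path)) {
    files <- setNames(file.path(path, paste0(tables, ".csv")), tables)
  } else {
    files <- unlist(path)
    if (!all(tables %in% names(files)))
      stop("catalog paths must name: ", paste(tables, collapse = ", "), call. = FALSE)
    files <- files[tables]
  }
  read1 <- function(f, tab) {
    if (!file.exists(f)) stop("catalog file not found: ", f, call. = FALSE)
    df <- tryCatch(read.csv(f, stringsAsFactors = FALSE, check.names = FALSE),
                   error = function(e) stop(sprintf("%s: %s", f, conditionMessage(e)),
                                            call. = FALSE))
    if (nrow(df) == 0L || ncol(df) == 0L)
      stop(sprintf("%s: empty %s table", f, tab), call. = FALSE)
    names(df)[1] <- "id"
    df
  }
  dfs <- Map(read1, files, tables)
  cat <- reagent_catalog(precatalysts = dfs$precatalysts$id,
                         ligands = dfs$ligands, additives = dfs$additives,
                         solvents = dfs$solvents, substrates = dfs$substrates)
  for (tab in tables) {
    df <- if (tab == "precatalysts") data.frame(id = cat$precatalysts) else cat[[tab]]
    nn <- which(!stats::complete.cases(df))
    if (length(nn))
      stop(sprintf("%s: missing/non-numeric value at row %d", files[[tab]], nn[1]),
           call. = FALSE)
  }
  cat
}

#' Write a reagent catalog to CSV files
#'
#' @param catalog a [reagent_catalog()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write.csv(df, file.path(dir, paste0(name, ".csv")),
                                    row.names = FALSE, quote = TRUE)
  w(data.frame(id = catalog$precatalysts), "precatalysts")
  w(catalog$ligands, "ligands")
  w(catalog$additives, "additives")
  w(catalog$solvents, "solvents")
  w(catalog$substrates, "substrates")
  invisible(dir)
}

#' Packaged example catalog
#'
#' A toy catalog with the study-sized inventories (5 precatalysts, 29
#' ligands, 14 additives including the additive-free control, 9 solvents)
#' and synthetic descriptor values generated once with a fixed seed. The
#' reagent identifiers are real; the descriptor numbers are not
#' physically computed and are packaged for testing and examples only.
#'
#' @return a [reagent_catalog()].
#' @export
example_catalog <- function() {
  read_catalog(system.file("extdata", "catalog", package = "atlrxn", mustWork = TRUE))
}
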