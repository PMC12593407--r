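RECORD_COLS <- c("amine_id", "acid_id", "precatalyst", "ligand", "additive",
                 "solvent", "yield_percent", "domain", "iteration")

#' Validate a table of reaction records
#'
#' A reaction record is one observed reaction: substrate pair, condition
#' tuple, assay yield in percent, a `domain` tag (`source` or `target`) and
#' an `iteration` index (0 = pre-campaign data).
#'
#' @param records data.frame with columns `amine_id`, `acid_id`,
#'   `precatalyst`, `ligand`, `additive`, `solvent`, `yield_percent`,
#'   `domain`, `iteration`.
#' @param catalog optional [reagent_catalog()]; when given, every identifier
#'   must resolve in it.
#' @return the validated data.frame (character identifier columns).
#' @export
reaction_records <- function(records, catalog = NULL) {
  records <- as.data.frame(records)
  miss <- setdiff(RECORD_COLS, names(records))
  if (length(miss))
    stop("reaction records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  records <- records[, RECORD_COLS]
  for (cl in setdiff(RECORD_COLS, c("yield_percent", "iteration")))
    records[[cl]] <- as.character(records[[cl]])
  records$yield_percent <- as.numeric(records$yield_percent)
  records$iteration <- as.integer(records$iteration)
  bad <- which(is.na(records$yield_percent) | records$yield_percent < 0 |
                 records$yield_percent > 100)
  if (length(bad))
    stop(sprintf("yield_percent outside [0, 100] at row %d", bad[1]), call. = FALSE)
  bad <- which(!records$domain %in% c("source", "target"))
  if (length(bad))
    stop(sprintf("domain must be 'source' or 'target' (row %d has '%s')",
                 bad[1], records$domain[bad[1]]), call. = FALSE)
  bad <- which(is.na(records$iteration) | records$iteration < 0L)
  if (length(bad))
    stop(sprintf("iteration must be a non-negative integer (row %d)", bad[1]),
         call. = FALSE)
  if (!is.null(catalog)) {
    for (cls in REAGENT_CLASSES)
      resolve_or_stop(records[[cls]], catalog_ids(catalog, cls), cls)
    resolve_or_stop(c(records$amine_id, records$acid_id),
                    catalog$substrates$id, "substrate")
  }
  rownames(records) <- NULL
  records
}

#' Read / write reaction records
#'
#' CSV with the canonical record columns; see [reaction_records()].
#'
#' @param path file path.
#' @inheritParams reaction_records
#' @return `read_records`: validated data.frame. `write_records`: `path`,
#'   invisibly.
#' @export
read_records <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  reaction_records(read.csv(path, stringsAsFactors = FALSE), catalog)
}

#' @rdname read_records
#' @param records data.frame of reaction records.
#' @export
write_records <- function(records, path) {
  records <- reaction_records(records)
  # 17 significant digits so yields survive the round trip bit-exactly
  records$yield_percent <- vapply(records$yield_percent, format, "",
                                  digits = 17, trim = TRUE)
  write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Label records against a yield threshold
#'
#' Builds the binary classification set the ensemble is trained on: label 1
#' iff the observed yield strictly exceeds `threshold_percent` — i.e. the
#' reaction improved on the previously optimized condition. The threshold is
#' stored with the set.
#'
#' @param records reaction records (validated against `catalog`).
#' @param threshold_percent baseline yield to beat, in percent.
#' @param catalog a [reagent_catalog()].
#' @param schema an [build_schema()] schema for the campaign's substrate
#'   pair; records are featurized with the *schema's* substrate pair
#'   descriptors when their own pair differs (source records from other
#'   substrates share the condition featurization).
#' @return an `atl_labeled_set`: list with `features` (matrix), `labels`
#'   (integer 0/1) and `threshold_percent`.
#' @export
label_records <- function(records, threshold_percent, catalog, schema) {
  records <- reaction_records(records, catalog)
  if (nrow(records) == 0L) stop("no records to label", call. = FALSE)
  X <- featurize_records(records, schema, catalog)
  structure(list(features = X,
                 labels = as.integer(records$yield_percent > threshold_percent),
                 threshold_percent = threshold_percent),
            class = "atl_labeled_set")
}

# Featurize records using each record's own substrate pair for the
# substrate blocks (source data may span several pairs), and the shared
# condition blocks for everything else.
featurize_records <- function(records, schema, catalog) {
  conds <- records[, REAGENT_CLASSES]
  X <- featurize(conds, schema$substrate_pair, schema, catalog)
  sub_m <- desc_matrix(catalog$substrates, skip = c("id", "role"))
  d <- ncol(sub_m)
  if (d > 0) {
    resolve_or_stop(c(records$amine_id, records$acid_id), rownames(sub_m),
                    "substrate")
    X[, seq_len(d)] <- sub_m[match(records$amine_id, rownames(sub_m)), ,
                             drop = FALSE]
    X[, d + seq_len(d)] <- sub_m[match(records$acid_id, rownames(sub_m)), ,
                                 drop = FALSE]
  }
  X
}
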