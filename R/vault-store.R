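# The "ADC Target Vault": typed ingestion of proteome, transmembrane
# prediction and IHC expression tables into an embedded indexed store
# (keyed data.tables, persistable as a single file) with the query
# primitives the ranking stage composes.

.proteome_cols <- c("protein_id", "gene_id", "gene_symbol")
.tm_cols <- c("protein_id", "predictor", "n_segments")
.healthy_cols <- c("protein_id", "tissue", "cell_type", "level")
.cancer_cols <- c("protein_id", "cancer_type", "n_high", "n_medium",
                  "n_low", "n_not_detected")

.read_tsv <- function(path, required, what) {
  if (!file.exists(path)) .stopf("%s table not found: %s", what, path)
  dt <- data.table::fread(path, sep = "\t")
  miss <- setdiff(required, names(dt))
  if (length(miss))
    .stopf("%s table '%s' is missing column(s): %s", what, path,
           paste(miss, collapse = ", "))
  dt
}

.check_referential <- function(child, parents, what) {
  bad <- setdiff(unique(child$protein_id), parents)
  if (length(bad))
    .stopf("referential integrity: %s table has %d protein_id value(s) not in the proteome: %s",
           what, length(bad),
           paste(utils::head(sort(bad), 10L), collapse = ", "))
}

#' Ingest annotation and expression tables into a target vault
#'
#' Reads the proteome, transmembrane-prediction, healthy-tissue IHC and
#' cancer IHC tab-separated tables, validates them (schema, referential
#' integrity against the proteome, controlled IHC vocabulary, non-negative
#' counts with at least one patient per summary), and returns an indexed
#' in-memory store. Indexes (data.table keys) are set on `protein_id`,
#' `tissue` and `cancer_type`. Ingest is idempotent: re-ingesting
#' identical files yields identical store contents.
#'
#' @param proteome,tm,healthy,cancer Paths to the four TSV tables (see
#'   [write_fixture_tables()] for the schemas).
#' @param db Optional path; when given, the store is also persisted there
#'   as a single file (readable with [vault_load()]).
#' @return An object of class `adc_vault`.
#' @export
vault_ingest <- function(proteome, tm, healthy, cancer, db = NULL) {
  prot <- .read_tsv(proteome, .proteome_cols, "proteome")
  if (any(!nzchar(prot$protein_id)) || anyNA(prot$protein_id))
    .stopf("proteome: protein_id must be non-empty")
  if (anyDuplicated(prot$protein_id))
    .stopf("proteome: duplicate protein_id values")
  if (any(!nzchar(prot$gene_symbol)) || anyNA(prot$gene_symbol))
    .stopf("proteome: gene_symbol must be non-empty")

  tmdt <- .read_tsv(tm, .tm_cols, "TM prediction")
  hea <- .read_tsv(healthy, .healthy_cols, "healthy IHC")
  can <- .read_tsv(cancer, .cancer_cols, "cancer IHC")

  .check_referential(tmdt, prot$protein_id, "TM prediction")
  .check_referential(hea, prot$protein_id, "healthy IHC")
  .check_referential(can, prot$protein_id, "cancer IHC")

  if (any(tmdt$n_segments < 0) || any(tmdt$n_segments != round(tmdt$n_segments)))
    .stopf("TM prediction: n_segments must be non-negative integers")
  if (anyDuplicated(tmdt[, c("protein_id", "predictor")]))
    .stopf("TM prediction: duplicate (protein_id, predictor) rows")

  bad_level <- which(is.na(match(tolower(gsub("[ _-]", "", hea$level)),
                                 tolower(ihc_levels()))))
  if (length(bad_level))
    .stopf("healthy IHC: malformed level at line(s) %s",
           paste(utils::head(bad_level + 1L, 10L), collapse = ", "))
  hea$level <- .normalize_level(hea$level)

  cnt <- as.matrix(can[, c("n_high", "n_medium", "n_low", "n_not_detected")])
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    .stopf("cancer IHC: counts must be non-negative integers")
  tot <- rowSums(cnt)
  if (any(tot < 1))
    .stopf("cancer IHC: total patients must be >= 1 at line(s) %s",
           paste(utils::head(which(tot < 1) + 1L, 10L), collapse = ", "))

  data.table::setkeyv(prot, "protein_id")
  data.table::setkeyv(tmdt, "protein_id")
  data.table::setkeyv(hea, c("protein_id", "tissue"))
  data.table::setkeyv(can, c("protein_id", "cancer_type"))
  data.table::setindexv(can, "cancer_type")

  vault <- structure(list(proteins = prot, tm = tmdt, healthy = hea,
                          cancer = can),
                     class = "adc_vault")
  if (!is.null(db)) vault_save(vault, db)
  vault
}

#' @export
print.adc_vault <- function(x, ...) {
  cat("<adc_vault>",
      sprintf("  proteins: %d", nrow(x$proteins)),
      sprintf("  TM predictions: %d", nrow(x$tm)),
      sprintf("  healthy IHC observations: %d", nrow(x$healthy)),
      sprintf("  cancer IHC summaries: %d (%s)", nrow(x$cancer),
              paste(unique(x$cancer$cancer_type), collapse = ", ")),
      sep = "\n")
  invisible(x)
}

#' Persist / load a vault as a single file
#'
#' @param vault An `adc_vault`.
#' @param path File path for the serialized store.
#' @return `vault_save` returns `path` invisibly; `vault_load` returns the
#'   `adc_vault`.
#' @export
vault_save <- function(vault, path) {
  stopifnot(inherits(vault, "adc_vault"))
  saveRDS(vault, path)
  invisible(path)
}

#' @rdname vault_save
#' @export
vault_load <- function(path) {
  if (!file.exists(path)) .stopf("vault file not found: %s", path)
  vault <- readRDS(path)
  if (!inherits(vault, "adc_vault")) .stopf("'%s' is not a vault file", path)
  vault
}

#' Export a vault back to its four TSV tables
#'
#' Round-trips the ingested tables: re-ingesting the exported files yields
#' an identical store (up to row order, which is fixed by the store keys).
#'
#' @param vault An `adc_vault`.
#' @param dir Output directory.
#' @return Invisibly, the named paths written.
#' @export
vault_export <- function(vault, dir) {
  stopifnot(inherits(vault, "adc_vault"))
  write_fixture_tables(list(proteins = vault$proteins, tm = vault$tm,
                            healthy = vault$healthy, cancer = vault$cancer),
                       dir)
}

#' Total patient count of a cancer IHC summary
#'
#' @param s A one-row cancer IHC summary (data.frame or list with fields
#'   `n_high`, `n_medium`, `n_low`, `n_not_detected`).
#' @return Integer total.
#' @export
patients_total <- function(s) {
  tot <- as.integer(s$n_high + s$n_medium + s$n_low + s$n_not_detected)
  if (any(tot < 1)) .stopf("cancer IHC summary must have >= 1 patient")
  tot
}

.vault_protein_exists <- function(vault, protein_id) {
  if (!protein_id %in% vault$proteins$protein_id)
    .stopf("protein '%s' not found in vault", protein_id)
}

#' Per-tissue healthy expression level for one protein
#'
#' Collapses a protein's healthy IHC observations to one level per tissue.
#' Under the default `collapse = "max"` each tissue is assigned the
#' maximum level over its cell types (the conservative choice for an
#' off-target safety screen); `collapse = "per_cell_type"` returns one row
#' per (tissue, cell type) pair instead.
#'
#' @param vault An `adc_vault`.
#' @param protein_id Protein accession present in the vault.
#' @param collapse `"max"` or `"per_cell_type"`.
#' @return For `"max"`, a named character vector (tissue -> level) over
#'   the tissues with at least one observation (empty if the protein has
#'   no healthy rows). For `"per_cell_type"`, a data.table of the
#'   protein's observations.
#' @export
healthy_level_by_tissue <- function(vault, protein_id,
                                    collapse = c("max", "per_cell_type")) {
  stopifnot(inherits(vault, "adc_vault"))
  collapse <- match.arg(collapse)
  .vault_protein_exists(vault, protein_id)
  .pid <- protein_id
  obs <- vault$healthy[list(.pid), on = "protein_id", nomatch = NULL]
  if (collapse == "per_cell_type") return(obs[])
  if (!nrow(obs)) return(stats::setNames(character(0), character(0)))
  agg <- obs[, list(level = ihc_levels()[max(.level_rank(level)) + 1L]),
             by = "tissue"]
  stats::setNames(agg$level, agg$tissue)
}
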