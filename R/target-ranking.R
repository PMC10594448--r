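# Candidate selection: single-pass transmembrane consensus filter, the
# >50% cancer-patient expression threshold, and four-key lexicographic
# ranking of candidates.

#' Transmembrane consensus filter
#'
#' Accepts a protein when at least `min_agree` of its (up to six)
#' predictor outputs report exactly `required_segments` membrane-spanning
#' segments. Missing predictor outputs count as disagreement, so a protein
#' with five predictions all reporting one segment still passes at the
#' default `min_agree = 5`.
#'
#' @param predictions TM-prediction rows for one protein (data.frame with
#'   `predictor` and `n_segments`), or a bare numeric vector of segment
#'   counts.
#' @param min_agree Minimum number of agreeing predictors (default 5 of 6).
#' @param required_segments Required segment count (default 1: single-pass).
#' @return Logical scalar.
#' @export
tm_consensus_filter <- function(predictions, min_agree = 5L,
                                required_segments = 1L) {
  if (is.data.frame(predictions)) {
    if (anyDuplicated(predictions$predictor))
      .stopf("duplicate predictor labels for one protein")
    n_seg <- predictions$n_segments
  } else {
    n_seg <- predictions
  }
  if (length(n_seg) > 6L)
    .stopf("at most 6 predictions per protein (got %d)", length(n_seg))
  sum(n_seg == required_segments) >= min_agree
}

#' Fraction of cancer patients at High or Medium expression
#'
#' @param s A cancer IHC summary (data.frame rows or list with counts
#'   `n_high`, `n_medium`, `n_low`, `n_not_detected`).
#' @return Numeric in `[0, 1]`, `(n_high + n_medium) / total`.
#' @export
patient_fraction <- function(s) {
  (s$n_high + s$n_medium) / patients_total(s)
}

#' Healthy-tissue expression counts for one protein
#'
#' Over the per-tissue maximum levels (see [healthy_level_by_tissue()]):
#' `K2` = number of tissues at High, `K3` = number at Medium, and
#' `K1 = K2 + K3` = number at High-or-Medium combined. A protein with no
#' healthy observations contributes zero to all three counts and is
#' flagged as a data gap.
#'
#' @inheritParams healthy_level_by_tissue
#' @return Named list with integers `K1`, `K2`, `K3` and logical
#'   `data_gap`.
#' @export
healthy_tissue_counts <- function(vault, protein_id) {
  levels_by_tissue <- healthy_level_by_tissue(vault, protein_id)
  K2 <- sum(levels_by_tissue == "High")
  K3 <- sum(levels_by_tissue == "Medium")
  list(K1 = as.integer(K2 + K3), K2 = as.integer(K2), K3 = as.integer(K3),
       data_gap = length(levels_by_tissue) == 0L)
}

#' Rank candidate ADC targets for a cancer type
#'
#' The candidate set consists of proteins whose fraction of cancer
#' patients at High-or-Medium expression strictly exceeds
#' `min_patient_fraction`, optionally intersected with the survivors of
#' [tm_consensus_filter()]. Candidates are ordered lexicographically by:
#' \enumerate{
#'   \item lowest number of healthy tissues at High-or-Medium (`K1`),
#'   \item lowest number of healthy tissues at High (`K2`),
#'   \item lowest number of healthy tissues at Medium (`K3`),
#'   \item highest fraction of patients at High-or-Medium (`K4`),
#' }
#' with residual ties broken by `gene_symbol` ascending (for determinism
#' only).
#'
#' @param vault An `adc_vault`.
#' @param cancer_type Cancer-type label present in the store.
#' @param min_patient_fraction Strict lower bound on the patient fraction
#'   (default 0.5; a protein at exactly the bound is excluded).
#' @param apply_tm_filter Apply the transmembrane consensus filter
#'   (default `TRUE`).
#' @param min_agree,required_segments Passed to [tm_consensus_filter()].
#' @return A data.table with columns `rank`, `protein_id`, `gene_symbol`,
#'   `K1`, `K2`, `K3`, `K4`, `passed_tm_filter`, `data_gap`, ordered by
#'   rank (1-based, consecutive). Empty (zero rows) when no candidate
#'   passes.
#' @export
rank_targets <- function(vault, cancer_type, min_patient_fraction = 0.5,
                         apply_tm_filter = TRUE, min_agree = 5L,
                         required_segments = 1L) {
  stopifnot(inherits(vault, "adc_vault"))
  if (!cancer_type %in% vault$cancer$cancer_type)
    .stopf("cancer_type '%s' not present in the vault", cancer_type)
  can <- vault$cancer[vault$cancer$cancer_type == cancer_type, ]
  frac <- patient_fraction(can)
  keep <- frac > min_patient_fraction
  cand_ids <- can$protein_id[keep]
  cand_frac <- frac[keep]

  empty <- data.table::data.table(
    rank = integer(0), protein_id = character(0), gene_symbol = character(0),
    K1 = integer(0), K2 = integer(0), K3 = integer(0), K4 = numeric(0),
    passed_tm_filter = logical(0), data_gap = logical(0))
  if (!length(cand_ids)) {
    message("rank_targets: no candidate passed the expression threshold")
    return(empty)
  }

  tm_pass <- vapply(cand_ids, function(pid) {
    preds <- vault$tm[list(pid), on = "protein_id", nomatch = NULL]
    tm_consensus_filter(preds, min_agree = min_agree,
                        required_segments = required_segments)
  }, logical(1))
  if (apply_tm_filter) {
    cand_ids <- cand_ids[tm_pass]
    cand_frac <- cand_frac[tm_pass]
    tm_pass <- tm_pass[tm_pass]
  }
  if (!length(cand_ids)) {
    message("rank_targets: no candidate survived the TM consensus filter")
    return(empty)
  }

  # one grouped pass over the healthy table: per-tissue max level, then
  # tissue counts per candidate (equivalent to healthy_tissue_counts())
  hea <- vault$healthy[vault$healthy$protein_id %in% cand_ids, ]
  agg <- if (nrow(hea))
    hea[, list(lvl = max(.level_rank(level))),
        by = c("protein_id", "tissue")]
  else data.table::data.table(protein_id = character(0),
                              tissue = character(0), lvl = integer(0))
  cnt <- agg[, list(K2 = sum(lvl == 3L), K3 = sum(lvl == 2L)),
             by = "protein_id"]
  idx <- match(cand_ids, cnt$protein_id)
  K2 <- ifelse(is.na(idx), 0L, cnt$K2[idx])
  K3 <- ifelse(is.na(idx), 0L, cnt$K3[idx])
  tab <- data.table::data.table(
    protein_id = cand_ids,
    gene_symbol = vault$proteins[list(cand_ids),
                                 on = "protein_id"]$gene_symbol,
    K1 = as.integer(K2 + K3), K2 = as.integer(K2), K3 = as.integer(K3),
    K4 = cand_frac,
    passed_tm_filter = unname(tm_pass),
    data_gap = is.na(idx))
  ord <- order(tab$K1, tab$K2, tab$K3, -tab$K4, tab$gene_symbol)
  tab <- tab[ord, ]
  tab[, rank := seq_len(.N)]
  data.table::setcolorder(tab, "rank")
  tab[]
}

#' Export a ranking table to CSV
#'
#' Comma-separated, LF line endings, header
#' `rank,protein_id,gene_symbol,K1,K2,K3,K4,passed_tm_filter,data_gap`;
#' `K4` is written with 4 decimal places.
#'
#' @param ranking A table from [rank_targets()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_ranking <- function(ranking, path) {
  out <- data.table::copy(ranking)
  out[, K4 := sprintf("%.4f", K4)]
  data.table::fwrite(out, path, sep = ",", eol = "\n", quote = FALSE)
  invisible(path)
}
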