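# Seeded generators for every input the pipeline consumes: proteome
# annotation with transmembrane predictions, healthy/cancer IHC expression,
# and GMT gene-set collections.  "Planted" proteins are constructed to be
# ideal ADC targets (single-pass TM consensus, >50% of patients at
# High/Medium, no healthy High/Medium tissue) so downstream stages have a
# known ground truth.

#' Configuration for the annotation/expression fixture generators
#'
#' Bundles every knob of the synthetic proteome, transmembrane-prediction
#' and IHC-expression generators. Defaults emulate the public-source tables
#' the pipeline was designed around: a 44-tissue healthy IHC panel (Human
#' Protein Atlas style), 22 patients per cancer type, and six
#' transmembrane-topology predictors (a TopCons-style consensus plus five
#' individual algorithms).
#'
#' @param seed Integer RNG seed; every generator is a pure function of its
#'   config including this seed.
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param n_planted_targets Number of planted ideal targets (must be
#'   `<= n_proteins`).
#' @param n_healthy_tissues Number of healthy tissues in the IHC panel.
#' @param n_patients Patients per cancer-type IHC summary.
#' @param predictor_names Exactly six transmembrane predictor labels.
#' @param cancer_types Valid cancer-type labels for [gen_expression()].
#' @param level_probs Named list of probability vectors over the four
#'   ordinal IHC levels (`NotDetected, Low, Medium, High`), one per
#'   stratum: `healthy_decoy`, `healthy_planted` (must place zero mass on
#'   Medium/High), and `cancer_decoy`. Each must sum to 1 within 1e-9.
#' @param decoy_multi_frac Fraction of decoy proteins given multi-pass or
#'   disagreeing transmembrane predictions (the rest are clean single-pass
#'   decoys that survive the TM filter but fail on expression).
#' @param max_cell_types Maximum number of cell types scored per healthy
#'   tissue (each tissue is assigned 1..`max_cell_types` cell types).
#'
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_proteins = 50L,
                           n_planted_targets = 5L,
                           n_healthy_tissues = 44L,
                           n_patients = 22L,
                           predictor_names = c("TOPCONS", "Philius",
                                               "PolyPhobius", "SPOCTOPUS",
                                               "OCTOPUS", "SCAMPI"),
                           cancer_types = "ovarian cancer",
                           level_probs = list(
                             healthy_decoy   = c(0.35, 0.35, 0.20, 0.10),
                             healthy_planted = c(0.70, 0.30, 0.00, 0.00),
                             cancer_decoy    = c(0.25, 0.25, 0.25, 0.25)),
                           decoy_multi_frac = 0.7,
                           max_cell_types = 3L) {
  seed <- .check_count(seed, "seed")
  n_proteins <- .check_count(n_proteins, "n_proteins", min = 1L)
  n_planted_targets <- .check_count(n_planted_targets, "n_planted_targets")
  if (n_planted_targets > n_proteins)
    .stopf("'n_planted_targets' (%d) must not exceed 'n_proteins' (%d)",
           n_planted_targets, n_proteins)
  n_healthy_tissues <- .check_count(n_healthy_tissues, "n_healthy_tissues",
                                    min = 1L)
  n_patients <- .check_count(n_patients, "n_patients", min = 1L)
  if (!is.character(predictor_names) || length(predictor_names) != 6L ||
      anyDuplicated(predictor_names))
    .stopf("'predictor_names' must be exactly 6 distinct labels")
  if (!is.character(cancer_types) || !length(cancer_types))
    .stopf("'cancer_types' must be a non-empty character vector")
  for (nm in c("healthy_decoy", "healthy_planted", "cancer_decoy")) {
    if (is.null(level_probs[[nm]]))
      .stopf("'level_probs' is missing stratum '%s'", nm)
    level_probs[[nm]] <- .check_prob_vector(level_probs[[nm]],
                                            paste0("level_probs$", nm))
  }
  if (any(level_probs$healthy_planted[3:4] > 0))
    .stopf("'level_probs$healthy_planted' must place zero mass on Medium/High")
  .check_scalar_num(decoy_multi_frac, "decoy_multi_frac", min = 0)
  if (decoy_multi_frac > 1) .stopf("'decoy_multi_frac' must be <= 1")
  max_cell_types <- .check_count(max_cell_types, "max_cell_types", min = 1L)
  structure(list(seed = seed, n_proteins = n_proteins,
                 n_planted_targets = n_planted_targets,
                 n_healthy_tissues = n_healthy_tissues,
                 n_patients = n_patients,
                 predictor_names = predictor_names,
                 cancer_types = cancer_types,
                 level_probs = level_probs,
                 decoy_multi_frac = decoy_multi_frac,
                 max_cell_types = max_cell_types),
            class = "fixture_config")
}

.subcell_vocab <- c("Cell membrane", "Cytoplasm", "Nucleus", "Golgi apparatus",
                    "Endoplasmic reticulum", "Mitochondrion", "Secreted",
                    "Lysosome", "Endosome")

#' Generate a synthetic proteome with transmembrane predictions
#'
#' Produces one annotation row per protein (accession, gene mapping,
#' subcellular localization, source transmembrane flag) and six
#' transmembrane-prediction rows per protein (one per predictor, reporting
#' the predicted number of membrane-spanning segments). Planted targets are
#' annotated as single-pass by at least five of the six predictors, so they
#' survive [tm_consensus_filter()] by construction. A fraction
#' `decoy_multi_frac` of decoys receives multi-pass or disagreeing
#' predictions; the remainder are clean single-pass decoys.
#'
#' @param cfg A [fixture_config()].
#' @return A list with `proteins` (data.table: `protein_id`, `gene_id`,
#'   `gene_symbol`, `subcellular_locations` (semicolon-joined),
#'   `is_transmembrane`, `planted`) and `tm` (data.table: `protein_id`,
#'   `predictor`, `n_segments`).
#' @export
gen_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_proteins
    k <- cfg$n_planted_targets
    protein_id <- sprintf("SP%05d", seq_len(n))
    gene_id <- sprintf("ENSG%011d", seq_len(n))
    gene_symbol <- sprintf("GS%04d", seq_len(n))
    planted <- c(rep(TRUE, k), rep(FALSE, n - k))

    locs <- vapply(seq_len(n), function(i) {
      extra <- sample(.subcell_vocab[-1], sample(0:2, 1))
      base <- if (planted[i]) "Cell membrane" else sample(.subcell_vocab, 1)
      paste(unique(c(base, extra)), collapse = ";")
    }, character(1))

    # decoy TM archetype: multi-pass/disagreeing vs clean single-pass
    decoy_multi <- rep(FALSE, n)
    if (n > k)
      decoy_multi[(k + 1):n] <-
        stats::runif(n - k) < cfg$decoy_multi_frac

    tm_rows <- lapply(seq_len(n), function(i) {
      if (planted[i]) {
        n_agree <- sample(5:6, 1)
        segs <- rep(1L, 6L)
        if (n_agree == 5L)
          segs[sample.int(6L, 1L)] <- sample(c(0L, 2L, 3L, 7L), 1L)
      } else if (decoy_multi[i]) {
        base <- sample(2:12, 1)
        segs <- pmax(0L, base + sample(-1:1, 6L, replace = TRUE))
        # a few pure disagreement decoys: scattered counts incl. some 1s
        if (stats::runif(1) < 0.3)
          segs <- sample(c(0L, 1L, 1L, 2L, 3L, 7L))
      } else {
        segs <- rep(1L, 6L)
      }
      data.table::data.table(protein_id = protein_id[i],
                             predictor = cfg$predictor_names,
                             n_segments = as.integer(segs))
    })
    tm <- data.table::rbindlist(tm_rows)

    is_tm <- vapply(split(tm$n_segments, tm$protein_id)[protein_id],
                    function(s) any(s > 0), logical(1))

    proteins <- data.table::data.table(
      protein_id = protein_id, gene_id = gene_id, gene_symbol = gene_symbol,
      subcellular_locations = locs,
      is_transmembrane = unname(is_tm), planted = planted)
    list(proteins = proteins, tm = tm)
  })
}

# deterministic healthy-tissue panel: labels are arbitrary, only counts matter
.tissue_panel <- function(n) sprintf("tissue_%02d", seq_len(n))

#' Generate healthy-tissue and cancer IHC expression tables
#'
#' Healthy observations cover every protein in every tissue of the panel,
#' with one row per (tissue, cell type) pair. Cancer rows summarise one
#' patient cohort per protein as counts over the four ordinal IHC levels,
#' plus staining intensity and quantity bins. Planted targets are drawn so
#' that strictly more than half the patients score High or Medium and no
#' healthy tissue scores above Low; decoys follow `cfg$level_probs`.
#'
#' @param cfg A [fixture_config()].
#' @param proteins The `proteins` table from [gen_proteome()].
#' @param cancer_type One of `cfg$cancer_types`.
#' @return A list with `healthy` (data.table: `protein_id`, `tissue`,
#'   `cell_type`, `level`) and `cancer` (data.table: `protein_id`,
#'   `cancer_type`, `n_high`, `n_medium`, `n_low`, `n_not_detected`,
#'   intensity counts `int_negative`..`int_strong`, quantity counts
#'   `qty_lt25`, `qty_25_75`, `qty_gt75`).
#' @export
gen_expression <- function(cfg, proteins, cancer_type = cfg$cancer_types[1]) {
  stopifnot(inherits(cfg, "fixture_config"), is.data.frame(proteins))
  if (!cancer_type %in% cfg$cancer_types)
    .stopf("unknown cancer_type '%s' (configured: %s)", cancer_type,
           paste(cfg$cancer_types, collapse = ", "))
  lv <- ihc_levels()
  # offset the stream from gen_proteome so both are pure in cfg alone
  .with_seed(cfg$seed + 1000003L, {
    tissues <- .tissue_panel(cfg$n_healthy_tissues)
    n_ct <- sample.int(cfg$max_cell_types, cfg$n_healthy_tissues,
                       replace = TRUE)
    tissue_tab <- data.table::data.table(
      tissue = rep(tissues, n_ct),
      cell_type = unlist(lapply(n_ct, function(m) sprintf("cell_%d",
                                                          seq_len(m)))))

    n_slots <- nrow(tissue_tab)
    healthy <- data.table::rbindlist(lapply(seq_len(nrow(proteins)),
                                            function(i) {
      pr <- if (proteins$planted[i]) cfg$level_probs$healthy_planted
            else cfg$level_probs$healthy_decoy
      data.table::data.table(
        protein_id = proteins$protein_id[i],
        tissue = tissue_tab$tissue,
        cell_type = tissue_tab$cell_type,
        level = sample(lv, n_slots, replace = TRUE, prob = pr))
    }))

    np <- cfg$n_patients
    cancer <- data.table::rbindlist(lapply(seq_len(nrow(proteins)),
                                           function(i) {
      if (proteins$planted[i]) {
        # High+Medium strictly exceeds half the cohort, by construction
        n_hm <- sample((np %/% 2L + 1L):np, 1L)
        n_high <- stats::rbinom(1L, n_hm, 0.65)
        n_medium <- n_hm - n_high
        n_low <- stats::rbinom(1L, np - n_hm, 0.5)
        n_nd <- np - n_hm - n_low
      } else {
        cnt <- stats::rmultinom(1L, np, cfg$level_probs$cancer_decoy)[, 1]
        n_nd <- cnt[1]; n_low <- cnt[2]; n_medium <- cnt[3]; n_high <- cnt[4]
      }
      ip <- if (proteins$planted[i]) c(0.05, 0.10, 0.35, 0.50)
            else c(0.25, 0.25, 0.25, 0.25)
      qp <- if (proteins$planted[i]) c(0.10, 0.25, 0.65)
            else c(1 / 3, 1 / 3, 1 / 3)
      ic <- stats::rmultinom(1L, np, ip)[, 1]
      qc <- stats::rmultinom(1L, np, qp)[, 1]
      data.table::data.table(
        protein_id = proteins$protein_id[i], cancer_type = cancer_type,
        n_high = n_high, n_medium = n_medium, n_low = n_low,
        n_not_detected = n_nd,
        int_negative = ic[1], int_weak = ic[2], int_moderate = ic[3],
        int_strong = ic[4],
        qty_lt25 = qc[1], qty_25_75 = qc[2], qty_gt75 = qc[3])
    }))
    list(healthy = healthy, cancer = cancer)
  })
}

#' Generate all annotation/expression fixture tables at once
#'
#' Convenience wrapper running [gen_proteome()] then [gen_expression()].
#'
#' @inheritParams gen_expression
#' @return A list with `proteins`, `tm`, `healthy`, `cancer`.
#' @export
gen_fixtures <- function(cfg, cancer_type = cfg$cancer_types[1]) {
  prot <- gen_proteome(cfg)
  expr <- gen_expression(cfg, prot$proteins, cancer_type)
  c(prot, expr)
}

#' Write fixture tables as tab-separated files
#'
#' @param fixtures A list from [gen_fixtures()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the four file paths
#'   (`proteome`, `tm`, `healthy`, `cancer`).
#' @export
write_fixture_tables <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(proteome = file.path(dir, "proteome.tsv"),
             tm = file.path(dir, "tm_predictions.tsv"),
             healthy = file.path(dir, "healthy_ihc.tsv"),
             cancer = file.path(dir, "cancer_ihc.tsv"))
  data.table::fwrite(fixtures$proteins, paths[["proteome"]], sep = "\t",
                     eol = "\n")
  data.table::fwrite(fixtures$tm, paths[["tm"]], sep = "\t", eol = "\n")
  data.table::fwrite(fixtures$healthy, paths[["healthy"]], sep = "\t",
                     eol = "\n")
  data.table::fwrite(fixtures$cancer, paths[["cancer"]], sep = "\t",
                     eol = "\n")
  invisible(paths)
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Builds `n_sets` gene sets over `universe`. The first set consists of
#' `planted_set_genes`; a query list is constructed containing
#' `query_overlap` of those genes plus random non-planted genes, so the
#' planted set is overrepresented in the query by construction.
#'
#' @param universe Character vector of gene symbols (the reference list).
#' @param n_sets Number of gene sets to generate (>= 1).
#' @param planted_set_genes Non-empty subset of `universe` forming the
#'   planted set.
#' @param query_overlap Number of planted genes placed in the query; must
#'   not exceed `length(planted_set_genes)`.
#' @param query_size Total query length (default 100, capped at the
#'   universe size).
#' @param seed Integer RNG seed.
#' @param set_size_range Length-2 integer range for random set sizes.
#' @return A list with `sets` (a [gene_set_collection()]) and `query`
#'   (character vector of gene symbols).
#' @export
gen_gene_sets <- function(universe, n_sets, planted_set_genes, query_overlap,
                          query_size = 100L, seed = 1L,
                          set_size_range = c(10L, 50L)) {
  if (!length(planted_set_genes))
    .stopf("'planted_set_genes' must be non-empty")
  if (!all(planted_set_genes %in% universe))
    .stopf("'planted_set_genes' must be a subset of 'universe'")
  n_sets <- .check_count(n_sets, "n_sets", min = 1L)
  query_overlap <- .check_count(query_overlap, "query_overlap", min = 0L)
  if (query_overlap > length(planted_set_genes))
    .stopf("'query_overlap' (%d) exceeds planted set size (%d)",
           query_overlap, length(planted_set_genes))
  query_size <- min(.check_count(query_size, "query_size", min = 1L),
                    length(universe))
  .with_seed(seed, {
    genes <- vector("list", n_sets)
    names(genes) <- c("PLANTED_SET",
                      if (n_sets > 1) sprintf("RANDOM_SET_%03d",
                                              seq_len(n_sets - 1L)))
    genes[[1L]] <- unique(planted_set_genes)
    if (n_sets > 1) {
      lo <- min(set_size_range); hi <- min(max(set_size_range),
                                           length(universe))
      for (j in 2:n_sets)
        genes[[j]] <- sample(universe, sample(lo:hi, 1L))
    }
    desc <- c("planted enriched set",
              if (n_sets > 1) rep("random background set", n_sets - 1L))
    names(desc) <- names(genes)

    non_planted <- setdiff(universe, planted_set_genes)
    n_fill <- min(query_size - query_overlap, length(non_planted))
    query <- c(sample(planted_set_genes, query_overlap),
               sample(non_planted, n_fill))
    list(sets = gene_set_collection(genes, desc), query = query)
  })
}
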