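# End-to-end pipeline runner: fixtures -> ingest -> rank -> ORA -> SPR,
# with per-stage logging to stderr and a machine-readable JSON run report.
# Outputs are bitwise-deterministic for identical configs (timings go to
# the log, never into artifacts).

#' Pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param fixture A [fixture_config()] describing the synthetic
#'   annotation/expression inputs.
#' @param spr A [sim_sensorgram_config()] for the SPR stage.
#' @param cancer_type Cancer type to rank (must be in
#'   `fixture$cancer_types`).
#' @param min_patient_fraction Strict expression threshold (default 0.5).
#' @param apply_tm_filter Apply the TM consensus filter (default `TRUE`).
#' @param top_n Number of top-ranked genes submitted to
#'   overrepresentation analysis (default 100).
#' @param fdr_threshold Significance threshold on BH-FDR (default 0.1).
#' @param n_gene_sets Number of synthetic gene sets (default 25).
#' @param seed Seed for the gene-set stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            fixture = fixture_config(),
                            spr = sim_sensorgram_config(),
                            cancer_type = fixture$cancer_types[1],
                            min_patient_fraction = 0.5,
                            apply_tm_filter = TRUE,
                            top_n = 100L,
                            fdr_threshold = 0.1,
                            n_gene_sets = 25L,
                            seed = 1L) {
  stopifnot(inherits(fixture, "fixture_config"),
            inherits(spr, "sim_sensorgram_config"))
  top_n <- .check_count(top_n, "top_n", min = 1L)
  .check_scalar_num(min_patient_fraction, "min_patient_fraction", min = 0)
  .check_scalar_num(fdr_threshold, "fdr_threshold", positive = TRUE)
  n_gene_sets <- .check_count(n_gene_sets, "n_gene_sets", min = 1L)
  seed <- .check_count(seed, "seed")
  if (!cancer_type %in% fixture$cancer_types)
    .stopf("cancer_type '%s' is not in fixture$cancer_types", cancer_type)
  structure(list(out_dir = out_dir, fixture = fixture, spr = spr,
                 cancer_type = cancer_type,
                 min_patient_fraction = min_patient_fraction,
                 apply_tm_filter = apply_tm_filter, top_n = top_n,
                 fdr_threshold = fdr_threshold,
                 n_gene_sets = n_gene_sets, seed = seed),
            class = "pipeline_config")
}

.log_stage <- function(stage, t0) {
  message(sprintf("[adcvault] %-10s done in %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full target-discovery pipeline
#'
#' Executes, in order: fixture generation (annotation, TM predictions,
#' IHC expression tables), ingestion into the vault, candidate ranking
#' with CSV export, overrepresentation analysis of the top-ranked genes
#' against a generated gene-set collection, and the SPR stage (sensorgram
#' simulation, double referencing, dissociation-only and full kinetic
#' fits). Identical configs produce bitwise-identical artifacts. Any
#' stage failure aborts with an error naming the stage.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the run report: a list of artifact paths, summary
#'   counts and per-stage status (also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    .log_stage(name, t0)
    res
  }

  config_path <- file.path(cfg$out_dir, "config.json")
  .write_json(.config_as_list(cfg), config_path)
  config_hash <- unname(tools::md5sum(config_path))

  fixtures <- stage("fixtures", {
    fix <- gen_fixtures(cfg$fixture, cfg$cancer_type)
    paths <- write_fixture_tables(fix, file.path(cfg$out_dir, "fixtures"))
    list(tables = fix, paths = paths)
  })

  vault <- stage("ingest", {
    p <- fixtures$paths
    vault_ingest(p[["proteome"]], p[["tm"]], p[["healthy"]], p[["cancer"]],
                 db = file.path(cfg$out_dir, "vault.rds"))
  })

  ranking_path <- file.path(cfg$out_dir, "ranking.csv")
  ranking <- stage("rank", {
    r <- rank_targets(vault, cfg$cancer_type,
                      min_patient_fraction = cfg$min_patient_fraction,
                      apply_tm_filter = cfg$apply_tm_filter)
    export_ranking(r, ranking_path)
    r
  })

  ora_path <- file.path(cfg$out_dir, "ora.tsv")
  ora_res <- stage("ora", {
    universe <- vault$proteins$gene_symbol
    top_n <- cfg$top_n
    if (top_n > nrow(ranking)) {
      warning(sprintf(
        "top_n (%d) exceeds the candidate count (%d); using all candidates",
        top_n, nrow(ranking)), call. = FALSE)
      top_n <- nrow(ranking)
    }
    query <- ranking$gene_symbol[seq_len(top_n)]
    gs <- gen_gene_sets(universe, cfg$n_gene_sets,
                        planted_set_genes = utils::head(query, 20L),
                        query_overlap = min(10L, length(query)),
                        seed = cfg$seed)
    write_gmt(gs$sets, file.path(cfg$out_dir, "gene_sets.gmt"))
    res <- ora(query, universe, gs$sets, min_size = 5L)
    data.table::fwrite(res, ora_path, sep = "\t", eol = "\n")
    res
  })

  spr_report_path <- file.path(cfg$out_dir, "spr_report.json")
  spr_fits <- stage("spr", {
    sg <- simulate_sensorgram(cfg$spr)
    write_sensorgram_csv(sg, file.path(cfg$out_dir, "sensorgram.csv"))
    corrected <- correct_sensorgram(sg)
    full <- fit_full_kinetics(corrected)
    offrate <- fit_dissociation(corrected, Rmax_for_pct = full$Rmax)
    .write_json(list(
      full_kinetics = .fit_as_list(full),
      offrate_screen = .fit_as_list(offrate)), spr_report_path)
    list(full = full, offrate = offrate)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("adcvault")),
    config_hash = config_hash,
    stages = c("fixtures", "ingest", "rank", "ora", "spr"),
    # artifact paths are stored relative to out_dir so the report is
    # byte-identical across runs in different locations
    paths = lapply(c(as.list(fixtures$paths),
                     list(vault = file.path(cfg$out_dir, "vault.rds"),
                          ranking = ranking_path, ora = ora_path,
                          sensorgram = file.path(cfg$out_dir,
                                                 "sensorgram.csv"),
                          spr_report = spr_report_path)),
                   .rel_to, base = cfg$out_dir),
    counts = list(
      n_proteins = nrow(vault$proteins),
      n_candidates = nrow(ranking),
      n_significant_pathways = nrow(ora_significant(ora_res,
                                                    cfg$fdr_threshold))),
    kinetics = list(ka = spr_fits$full$ka, kd = spr_fits$full$kd,
                    KD = spr_fits$full$KD, Rmax = spr_fits$full$Rmax,
                    chi2_pct = spr_fits$full$chi2_pct))
  .write_json(report, file.path(cfg$out_dir, "run_report.json"))
  invisible(report)
}

.rel_to <- function(path, base) {
  base <- paste0(sub("/+$", "", base), "/")
  sub(base, "", path, fixed = TRUE)
}

.config_as_list <- function(cfg) {
  list(fixture = unclass(cfg$fixture), spr = unclass(cfg$spr),
       cancer_type = cfg$cancer_type,
       min_patient_fraction = cfg$min_patient_fraction,
       apply_tm_filter = cfg$apply_tm_filter, top_n = cfg$top_n,
       fdr_threshold = cfg$fdr_threshold, n_gene_sets = cfg$n_gene_sets,
       seed = cfg$seed)
}

.fit_as_list <- function(fit) {
  list(mode = fit$mode, ka = fit$ka, kd = fit$kd, KD = fit$KD,
       Rmax = fit$Rmax, R0 = as.list(fit$R0), chi2 = fit$chi2,
       chi2_pct = fit$chi2_pct, high_significance = fit$high_significance,
       rmax_source = fit$rmax_source, n_points = fit$n_points,
       n_params = fit$n_params, converged = fit$converged)
}
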