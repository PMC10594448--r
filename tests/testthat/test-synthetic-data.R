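test_that("proteome generator: counts, determinism, planted TM consensus", {
  cfg <- fixture_config(seed = 1, n_proteins = 50, n_planted_targets = 5)
  out <- gen_proteome(cfg)
  expect_equal(nrow(out$proteins), 50L)
  expect_equal(nrow(out$tm), 300L)  # 6 predictors per protein
  expect_equal(unname(table(out$tm$protein_id))[1], 6L,
               ignore_attr = TRUE)
  expect_false(anyDuplicated(out$proteins$gene_symbol) > 0)

  again <- gen_proteome(cfg)
  expect_identical(out, again)

  for (pid in out$proteins$protein_id[out$proteins$planted]) {
    preds <- out$tm[out$tm$protein_id == pid, ]
    expect_true(tm_consensus_filter(preds))
  }
})

test_that("fixture config validation names the offending field", {
  expect_error(fixture_config(n_proteins = 10, n_planted_targets = 11),
               "n_planted_targets")
  expect_error(fixture_config(predictor_names = letters[1:5]),
               "predictor_names")
  expect_error(
    fixture_config(level_probs = list(healthy_decoy = c(0.5, 0.5, 0.1, 0),
                                      healthy_planted = c(0.7, 0.3, 0, 0),
                                      cancer_decoy = rep(0.25, 4))),
    "healthy_decoy")
  expect_error(fixture_config(seed = 1.5), "seed")
})

test_that("expression generator: planted truth holds in every stratum", {
  cfg <- fixture_config(seed = 11, n_proteins = 30, n_planted_targets = 4,
                        n_patients = 22)
  prot <- gen_proteome(cfg)$proteins
  expr <- gen_expression(cfg, prot)
  planted_ids <- prot$protein_id[prot$planted]

  can <- expr$cancer
  for (pid in planted_ids) {
    row <- can[can$protein_id == pid, ]
    # >0.5 of 22 patients forces at least 12 at High+Medium
    expect_gte(row$n_high + row$n_medium, 12L)
    # planted targets have zero healthy tissues above Low
    h <- expr$healthy[expr$healthy$protein_id == pid, ]
    expect_true(all(h$level %in% c("NotDetected", "Low")))
  }
  # coverage: every protein has one cancer summary and all tissues observed
  expect_setequal(can$protein_id, prot$protein_id)
  n_tissues <- tapply(expr$healthy$tissue, expr$healthy$protein_id,
                      function(t) length(unique(t)))
  expect_true(all(n_tissues == cfg$n_healthy_tissues))
  # patient counts always total the cohort size
  tot <- can$n_high + can$n_medium + can$n_low + can$n_not_detected
  expect_true(all(tot == 22L))

  expect_error(gen_expression(cfg, prot, cancer_type = "lung cancer"),
               "unknown cancer_type")
})

test_that("decoy healthy levels follow the configured distribution", {
  # uniform levels, one cell type per tissue: tissue High-or-Medium count
  # is Binomial(44, 0.5); check the realized count against exact 99%
  # bounds and the pooled level frequencies against multinomial bounds
  cfg <- fixture_config(seed = 7, n_proteins = 40, n_planted_targets = 0,
                        n_healthy_tissues = 44, max_cell_types = 1,
                        level_probs = list(healthy_decoy = rep(0.25, 4),
                                           healthy_planted = c(0.7, 0.3, 0, 0),
                                           cancer_decoy = rep(0.25, 4)))
  fix <- gen_fixtures(cfg)
  lvmap <- c(NotDetected = 0, Low = 1, Medium = 2, High = 3)
  hm_counts <- tapply(lvmap[fix$healthy$level] >= 2,
                      fix$healthy$protein_id, sum)
  lo <- qbinom(0.005, 44, 0.5)
  hi <- qbinom(0.995, 44, 0.5)
  # individual counts hover around 22; the mean must sit well inside
  expect_gt(mean(hm_counts), lo)
  expect_lt(mean(hm_counts), hi)
  # pooled frequency of each level over 40*44 draws, 99.9% binomial bounds
  n <- nrow(fix$healthy)
  freq <- table(factor(fix$healthy$level, levels = names(lvmap))) / n
  bound <- qbinom(c(5e-4, 1 - 5e-4), n, 0.25) / n
  expect_true(all(freq >= bound[1] & freq <= bound[2]))
})

test_that("gene-set generator plants a recoverable enrichment", {
  universe <- sprintf("G%04d", 1:1000)
  planted <- universe[1:20]
  gs <- gen_gene_sets(universe, n_sets = 10, planted_set_genes = planted,
                      query_overlap = 10, query_size = 100, seed = 3)
  res <- ora(gs$query, universe, gs$sets, min_size = 5)
  expect_equal(res$set_name[1], "PLANTED_SET")
  # cross-check the top p-value with Fisher's exact test
  top <- res[res$set_name == "PLANTED_SET", ]
  ft <- fisher.test(matrix(c(top$k, top$q - top$k, top$m - top$k,
                             top$N - top$m - top$q + top$k), 2),
                    alternative = "greater")
  expect_equal(top$p_value, ft$p.value, tolerance = 1e-12)

  expect_error(gen_gene_sets(universe, 5, character(0), 1), "non-empty")
  expect_error(gen_gene_sets(universe, 5, planted, 21), "exceeds")

  one <- gen_gene_sets(universe, 1, planted, 5, seed = 1)
  path <- withr::local_tempfile()
  write_gmt(one$sets, path)
  expect_length(readLines(path), 1L)
})

test_that("sensorgram simulator: noiseless traces equal the 1:1 model", {
  cfg <- sim_sensorgram_config(ka = 1e5, kd = 1e-3, Rmax = 80,
                               concentrations = 5e-8, t_assoc = 60,
                               t_dissoc = 120, dt = 1)
  sg <- simulate_sensorgram(cfg)
  act <- sg[sg$role == "active" & sg$phase == "assoc", ]
  expect_equal(act$response_RU,
               model_association(act$t_s, 1e5, 1e-3, 5e-8, 80))
  dis <- sg[sg$role == "active" & sg$phase == "dissoc", ]
  r0 <- model_association(60, 1e5, 1e-3, 5e-8, 80)
  expect_equal(dis$response_RU, model_dissociation(dis$t_s, 1e-3, r0))
  # reference and blank traces carry no binding signal
  expect_true(all(sg$response_RU[sg$role == "reference"] == 0))
  expect_true(all(sg$response_RU[grepl("blank", sg$phase)] == 0))
})

test_that("sensorgram simulator: equilibrium at C = KD is Rmax/2", {
  ka <- 3.68e5; kd <- 4e-4          # antibody off-rate screen regime
  KD <- kd / ka
  cfg <- sim_sensorgram_config(ka = ka, kd = kd, Rmax = 100,
                               concentrations = KD, t_assoc = 2e5,
                               t_dissoc = 10, dt = 1e4)
  sg <- simulate_sensorgram(cfg)
  act <- sg[sg$role == "active" & sg$phase == "assoc", ]
  expect_equal(act$response_RU[which.max(act$t_s)], 50, tolerance = 1e-9)
})

test_that("sensorgram simulator is deterministic under a fixed seed", {
  cfg <- sim_sensorgram_config(noise_sd = 1.5, drift_slope = 0.01,
                               bulk_shift = 20, seed = 42)
  expect_identical(simulate_sensorgram(cfg), simulate_sensorgram(cfg))
  cfg2 <- sim_sensorgram_config(noise_sd = 1.5, seed = 43)
  expect_false(identical(simulate_sensorgram(cfg2),
                         simulate_sensorgram(cfg)))
  expect_error(sim_sensorgram_config(concentrations = c(2e-8, 1e-8)),
               "increasing")
  expect_error(sim_sensorgram_config(ka = -1), "ka")
})
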