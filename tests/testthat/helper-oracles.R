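# Shared fixtures and independent oracles for the test suite.  The
# oracles are deliberately written in plain base R, independent of the
# package code paths they check.

# --- vault construction helpers ---------------------------------------

# write arbitrary tables as TSVs and ingest them
make_vault_from_tables <- function(proteins, tm, healthy, cancer,
                                   dir = withr::local_tempdir(
                                     .local_envir = parent.frame())) {
  paths <- write_fixture_tables(list(proteins = proteins, tm = tm,
                                     healthy = healthy, cancer = cancer),
                                dir)
  vault_ingest(paths[["proteome"]], paths[["tm"]], paths[["healthy"]],
               paths[["cancer"]])
}

make_vault_from_fixtures <- function(fix, ...) {
  make_vault_from_tables(fix$proteins, fix$tm, fix$healthy, fix$cancer, ...)
}

# minimal hand-built tables: one protein row per id, all predictors
# single-pass, cancer counts and per-tissue healthy levels as given
tiny_tables <- function(cancer_counts, healthy_levels = list(),
                        cancer_type = "ovarian cancer") {
  ids <- names(cancer_counts)
  proteins <- data.frame(protein_id = ids,
                         gene_id = paste0("ENSG", seq_along(ids)),
                         gene_symbol = paste0("G", seq_along(ids)),
                         subcellular_locations = "Cell membrane",
                         is_transmembrane = TRUE, planted = FALSE)
  tm <- do.call(rbind, lapply(ids, function(p)
    data.frame(protein_id = p, predictor = paste0("P", 1:6),
               n_segments = 1L)))
  hl <- do.call(rbind, lapply(ids, function(p) {
    h <- healthy_levels[[p]]
    if (is.null(h)) return(NULL)
    data.frame(protein_id = p, tissue = h$tissue, cell_type = h$cell_type,
               level = h$level)
  }))
  if (is.null(hl))  # every protein needs >= 1 healthy row for ingest? no:
    hl <- data.frame(protein_id = character(0), tissue = character(0),
                     cell_type = character(0), level = character(0))
  cn <- do.call(rbind, lapply(ids, function(p) {
    cc <- cancer_counts[[p]]
    data.frame(protein_id = p, cancer_type = cancer_type,
               n_high = cc[1], n_medium = cc[2], n_low = cc[3],
               n_not_detected = cc[4])
  }))
  list(proteins = proteins, tm = tm, healthy = hl, cancer = cn)
}

# --- independent oracles ----------------------------------------------

# brute-force 4-key lexicographic ranking straight from the fixture
# tables (no vault, no package query code)
brute_rank <- function(fix, cancer_type, min_frac = 0.5, apply_tm = TRUE,
                       min_agree = 5, req_seg = 1) {
  can <- as.data.frame(fix$cancer)
  can <- can[can$cancer_type == cancer_type, ]
  tot <- can$n_high + can$n_medium + can$n_low + can$n_not_detected
  frac <- (can$n_high + can$n_medium) / tot
  keep <- frac > min_frac
  ids <- can$protein_id[keep]
  frac <- frac[keep]
  tm <- as.data.frame(fix$tm)
  if (apply_tm && length(ids)) {
    pass <- vapply(ids, function(p)
      sum(tm$n_segments[tm$protein_id == p] == req_seg) >= min_agree,
      logical(1))
    ids <- ids[pass]; frac <- frac[pass]
  }
  if (!length(ids))
    return(data.frame(protein_id = character(0), K1 = integer(0),
                      K2 = integer(0), K3 = integer(0), K4 = numeric(0)))
  hea <- as.data.frame(fix$healthy)
  lvmap <- c(NotDetected = 0, Low = 1, Medium = 2, High = 3)
  keys <- t(vapply(ids, function(p) {
    h <- hea[hea$protein_id == p, ]
    if (!nrow(h)) return(c(0, 0, 0))
    mx <- tapply(lvmap[h$level], h$tissue, max)
    c(sum(mx >= 2), sum(mx == 3), sum(mx == 2))
  }, numeric(3)))
  gs <- fix$proteins$gene_symbol[match(ids, fix$proteins$protein_id)]
  o <- order(keys[, 1], keys[, 2], keys[, 3], -frac, gs)
  data.frame(protein_id = ids[o], K1 = keys[o, 1], K2 = keys[o, 2],
             K3 = keys[o, 3], K4 = frac[o], row.names = NULL)
}

# hypergeometric upper tail P[X >= k] by direct pmf summation
hyper_upper_tail <- function(k, m, q, N) {
  if (k <= 0) return(1)
  i <- k:min(m, q)
  sum(exp(lchoose(m, i) + lchoose(N - m, q - i) - lchoose(N, q)))
}

# classical fourth-order Runge-Kutta integration of the 1:1 binding ODE
# dR/dt = ka*C*(Rmax - R) - kd*R from R(0) = 0 up to t_end
rk4_association <- function(t_end, ka, kd, C, Rmax, dt = 0.01) {
  f <- function(R) ka * C * (Rmax - R) - kd * R
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  R <- 0
  for (i in seq_len(n)) {
    k1 <- f(R)
    k2 <- f(R + dt / 2 * k1)
    k3 <- f(R + dt / 2 * k2)
    k4 <- f(R + dt * k3)
    R <- R + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  R
}
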