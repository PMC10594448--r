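# Multi-cycle Biacore-style sensorgram simulator: a 1:1 Langmuir binding
# signal on the active flow cell plus the standard instrument artefacts
# (linear baseline drift, a rectangular bulk refractive-index shift during
# the injection, i.i.d. Gaussian noise) on all flow cells, with a
# buffer-only blank cycle pair for double referencing.

#' Configuration for the sensorgram simulator
#'
#' Defaults follow a typical antibody off-rate screen: 120 s injection,
#' 600 s dissociation, a five-point two-fold concentration series run in
#' increasing order, and kinetic constants in the regime of high-affinity
#' antibody/antigen pairs (ka ~ 3.7e5 1/(M s), kd between 8e-5 and 4e-4
#' 1/s).
#'
#' @param ka Association rate constant, 1/(M s); > 0.
#' @param kd Dissociation rate constant, 1/s; > 0.
#' @param Rmax Saturation response, resonance units (RU); > 0.
#' @param concentrations Strictly increasing positive analyte
#'   concentrations, molar.
#' @param t_assoc,t_dissoc Association / dissociation durations, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Additive Gaussian noise standard deviation, RU.
#' @param drift_slope Linear baseline drift, RU/s (applied over the whole
#'   cycle on every flow cell).
#' @param bulk_shift Rectangular refractive-index step during the
#'   association phase, RU (every flow cell).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_sensorgram_config`.
#' @export
sim_sensorgram_config <- function(ka = 3.68e5, kd = 4e-4, Rmax = 100,
                                  concentrations = 7.8125e-9 * 2^(0:4),
                                  t_assoc = 120, t_dissoc = 600, dt = 1,
                                  noise_sd = 0, drift_slope = 0,
                                  bulk_shift = 0, seed = 1L) {
  .check_scalar_num(ka, "ka", positive = TRUE)
  .check_scalar_num(kd, "kd", positive = TRUE)
  .check_scalar_num(Rmax, "Rmax", positive = TRUE)
  if (!is.numeric(concentrations) || !length(concentrations) ||
      any(concentrations <= 0))
    .stopf("'concentrations' must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    .stopf("'concentrations' must be strictly increasing")
  .check_scalar_num(t_assoc, "t_assoc", positive = TRUE)
  .check_scalar_num(t_dissoc, "t_dissoc", positive = TRUE)
  .check_scalar_num(dt, "dt", positive = TRUE)
  .check_scalar_num(noise_sd, "noise_sd", min = 0)
  .check_scalar_num(drift_slope, "drift_slope")
  .check_scalar_num(bulk_shift, "bulk_shift")
  seed <- .check_count(seed, "seed")
  structure(list(ka = ka, kd = kd, Rmax = Rmax,
                 concentrations = as.numeric(concentrations),
                 t_assoc = t_assoc, t_dissoc = t_dissoc, dt = dt,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 bulk_shift = bulk_shift, seed = seed),
            class = "sim_sensorgram_config")
}

# one flow-cell trace for one cycle: artefacts everywhere, binding only on
# the active cell of a non-blank cycle
.sim_trace <- function(cfg, conc, role, blank) {
  ta <- seq(0, cfg$t_assoc, by = cfg$dt)
  td <- seq(0, cfg$t_dissoc, by = cfg$dt)
  bind_a <- rep(0, length(ta))
  bind_d <- rep(0, length(td))
  if (!blank && role == "active" && conc > 0) {
    bind_a <- model_association(ta, cfg$ka, cfg$kd, conc, cfg$Rmax)
    r0 <- model_association(cfg$t_assoc, cfg$ka, cfg$kd, conc, cfg$Rmax)
    bind_d <- model_dissociation(td, cfg$kd, r0)
  }
  drift_a <- cfg$drift_slope * ta
  drift_d <- cfg$drift_slope * (cfg$t_assoc + td)
  bulk_a <- rep(cfg$bulk_shift, length(ta))
  resp_a <- bind_a + drift_a + bulk_a
  resp_d <- bind_d + drift_d
  if (cfg$noise_sd > 0) {
    resp_a <- resp_a + stats::rnorm(length(ta), sd = cfg$noise_sd)
    resp_d <- resp_d + stats::rnorm(length(td), sd = cfg$noise_sd)
  }
  phase_a <- if (blank) "blank_assoc" else "assoc"
  phase_d <- if (blank) "blank_dissoc" else "dissoc"
  data.table::data.table(
    flow_cell = if (role == "active") "FC2" else "FC1",
    role = role,
    phase = c(rep(phase_a, length(ta)), rep(phase_d, length(td))),
    conc_M = conc, t_s = c(ta, td), response_RU = c(resp_a, resp_d))
}

#' Simulate a multi-cycle SPR sensorgram
#'
#' Emits, per concentration, an active-flow-cell and a reference-flow-cell
#' trace, plus one buffer-only blank cycle pair for the whole series
#' (cycle id 0, concentration 0). The active trace follows the 1:1
#' Langmuir model ([model_association()], [model_dissociation()]) plus the
#' configured drift, bulk shift and noise; reference and blank traces
#' carry the artefacts only. Time is sampled at `t = 0, dt, 2dt, ...`
#' within each phase, with dissociation re-zeroed at injection end.
#'
#' @param cfg A [sim_sensorgram_config()].
#' @return A data.table with columns `cycle_id`, `flow_cell`, `role`
#'   (`active`/`reference`), `phase` (`assoc`/`dissoc`/`blank_assoc`/
#'   `blank_dissoc`), `conc_M`, `t_s`, `response_RU`.
#' @export
simulate_sensorgram <- function(cfg) {
  stopifnot(inherits(cfg, "sim_sensorgram_config"))
  .with_seed(cfg$seed, {
    out <- vector("list", 2L * length(cfg$concentrations) + 2L)
    j <- 0L
    # blank cycle pair first (run order does not matter to referencing)
    for (role in c("active", "reference")) {
      j <- j + 1L
      tr <- .sim_trace(cfg, 0, role, blank = TRUE)
      tr[, cycle_id := 0L]
      out[[j]] <- tr
    }
    for (i in seq_along(cfg$concentrations)) {
      for (role in c("active", "reference")) {
        j <- j + 1L
        tr <- .sim_trace(cfg, cfg$concentrations[i], role, blank = FALSE)
        tr[, cycle_id := i]
        out[[j]] <- tr
      }
    }
    sg <- data.table::rbindlist(out)
    data.table::setcolorder(sg, c("cycle_id", "flow_cell", "role", "phase",
                                  "conc_M", "t_s", "response_RU"))
    sg[]
  })
}

#' Write / read a sensorgram table as CSV
#'
#' Plain comma-separated text with header
#' `cycle_id,flow_cell,role,phase,conc_M,t_s,response_RU`.
#'
#' @param sg A sensorgram data.table from [simulate_sensorgram()].
#' @param path File path.
#' @return `write_sensorgram_csv` returns `path` invisibly;
#'   `read_sensorgram_csv` returns the sensorgram data.table.
#' @export
write_sensorgram_csv <- function(sg, path) {
  data.table::fwrite(sg, path, sep = ",", eol = "\n")
  invisible(path)
}

#' @rdname write_sensorgram_csv
#' @export
read_sensorgram_csv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sg <- data.table::fread(path)
  need <- c("cycle_id", "flow_cell", "role", "phase", "conc_M", "t_s",
            "response_RU")
  miss <- setdiff(need, names(sg))
  if (length(miss))
    .stopf("sensorgram CSV is missing column(s): %s",
           paste(miss, collapse = ", "))
  sg
}
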