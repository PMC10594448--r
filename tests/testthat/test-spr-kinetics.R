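test_that("association model: boundary values and equilibrium", {
  expect_equal(model_association(0, 1e5, 1e-3, 1e-8, 100), 0)
  expect_equal(model_association(0, 1e5, 1e-3, 1e-8, 100, R_init = 7), 7)
  # t -> Inf at C = KD gives Rmax/2
  ka <- 3.68e5; kd <- 4e-4
  expect_equal(model_association(1e9, ka, kd, kd / ka, 100), 50,
               tolerance = 1e-12)
  # C = 0 from a bare surface stays at zero
  expect_equal(model_association(c(0, 10, 100), 1e5, 1e-3, 0, 100),
               c(0, 0, 0))
  expect_error(model_association(1, -1e5, 1e-3, 1e-8, 100), "ka")
  expect_error(model_association(-1, 1e5, 1e-3, 1e-8, 100), "'t'")
})

test_that("association model agrees with RK4 integration of the rate ODE", {
  skip_if_not_installed("deSolve")
  # antibody/antigen regime: ka ~ 3.6e5 1/(M s), kd in [8e-5, 4e-4] 1/s
  for (C in c(7.8e-9, 6.25e-8, 2.5e-7)) {
    for (kd in c(8e-5, 4e-4)) {
      closed <- model_association(120, 3.68e5, kd, C, 100)
      ode <- deSolve::ode(
        y = c(R = 0), times = c(0, 120),
        func = function(t, y, p) list(3.68e5 * C * (100 - y) - kd * y),
        parms = NULL, method = "ode45", atol = 1e-12, rtol = 1e-12)
      expect_equal(closed, unname(ode[2, "R"]), tolerance = 1e-8)
      # and the hand-written RK4 oracle
      expect_equal(closed, rk4_association(120, 3.68e5, kd, C, 100),
                   tolerance = 1e-8)
    }
  }
})

test_that("dissociation model: exponential decay identities", {
  expect_equal(model_dissociation(0, 4e-4, 123), 123)
  # half-life: t = ln 2 / kd
  expect_equal(model_dissociation(log(2) / 4e-4, 4e-4, 80), 40)
  # slow off-rate end of the screen: exp(-8e-5 * 600)
  expect_equal(model_dissociation(600, 8e-5, 1), exp(-0.048))
  expect_true(all(diff(model_dissociation(0:600, 4e-4, 50)) <= 0))
  expect_error(model_dissociation(1, -2e-4, 50), "kd")
})

test_that("double referencing cancels shared artefacts exactly", {
  tt <- seq(0, 60, 0.5)
  trace <- function(resp_a, resp_d) {
    data.frame(phase = rep(c("assoc", "dissoc"), each = length(tt)),
               t_s = c(tt, tt), response_RU = c(resp_a, resp_d))
  }
  zero <- trace(rep(0, length(tt)), rep(0, length(tt)))
  act <- trace(sin(tt), cos(tt))
  # active == reference with zero blanks -> all-zero corrected trace
  corr <- double_reference(act, act, zero, zero)
  expect_equal(corr$response_RU, rep(0, 2 * length(tt)))
  # identical drift in all four traces cancels algebraically
  drift <- trace(0.05 * tt + 3, 0.05 * (60 + tt) + 3)
  corr2 <- double_reference(drift, drift, drift, drift)
  expect_equal(corr2$response_RU, rep(0, 2 * length(tt)))
  # non-overlapping time ranges are an alignment error
  short <- trace(sin(tt), cos(tt))
  short <- short[short$t_s <= 30, ]
  expect_error(double_reference(act, short, zero, zero), "alignment")
})

test_that("double-referenced simulator output recovers the pure model", {
  cfg <- sim_sensorgram_config(ka = 3.68e5, kd = 4e-4, Rmax = 100,
                               noise_sd = 0, drift_slope = 0.02,
                               bulk_shift = 35)
  corrected <- correct_sensorgram(simulate_sensorgram(cfg))
  for (cid in unique(corrected$cycle_id)) {
    cyc <- corrected[corrected$cycle_id == cid, ]
    C <- cyc$conc_M[1]
    a <- cyc[cyc$phase == "assoc", ]
    expect_equal(a$response_RU,
                 model_association(a$t_s, cfg$ka, cfg$kd, C, cfg$Rmax),
                 tolerance = 1e-9)
    d <- cyc[cyc$phase == "dissoc", ]
    r0 <- model_association(cfg$t_assoc, cfg$ka, cfg$kd, C, cfg$Rmax)
    expect_equal(d$response_RU, model_dissociation(d$t_s, cfg$kd, r0),
                 tolerance = 1e-9)
  }
})

test_that("chi2 statistics follow the degrees-of-freedom convention", {
  expect_equal(chi2_stat(rep(0, 10), 3), 0)
  expect_equal(chi2_stat(c(1, -1, 1, -1), 2), 2)
  expect_equal(chi2_stat(c(1, -1, 1, -1), 2, normalize = "raw"), 4)
  expect_error(chi2_stat(c(1, 2), 2), "n_points > n_params")
  # large-n consistency: chi2 -> sigma^2
  set.seed(1)
  r <- rnorm(20000, sd = 1.5)
  expect_equal(chi2_stat(r, 3), 1.5^2, tolerance = 0.05)
})

test_that("chi2 percent applies the below-5% high-significance rule", {
  p <- chi2_percent(2, 100)
  expect_equal(p$value, 2)
  expect_true(p$high_significance)
  p2 <- chi2_percent(6, 100)
  expect_equal(p2$value, 6)
  expect_false(p2$high_significance)
  expect_equal(chi2_percent(0, 50)$value, 0)
  expect_error(chi2_percent(2, 0), "Rmax")
})

test_that("noiseless dissociation fit recovers kd to high precision", {
  cfg <- sim_sensorgram_config(ka = 3.68e5, kd = 4e-4, Rmax = 100)
  corrected <- correct_sensorgram(simulate_sensorgram(cfg))
  fit <- fit_dissociation(corrected)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd - 4e-4) / 4e-4, 1e-6)
  expect_lt(fit$chi2, 1e-12)
  expect_equal(fit$rmax_source, "max_R0")

  # single exact exponential: chi2 = 0 up to solver tolerance
  one <- data.frame(cycle_id = 1, conc_M = 1e-8, phase = "dissoc",
                    t_s = 0:600,
                    response_RU = model_dissociation(0:600, 2e-4, 80))
  f1 <- fit_dissociation(one, t_exclude = 0)
  expect_lt(f1$chi2, 1e-18)
  expect_equal(f1$kd, 2e-4, tolerance = 1e-8)
  expect_equal(unname(f1$R0), 80, tolerance = 1e-8)

  zero <- one
  zero$response_RU <- 0
  expect_error(fit_dissociation(zero), "degenerate")
})

test_that("noiseless full kinetic fit recovers ka, kd and Rmax", {
  # slow off-rate / PCDHB10-like regime
  cfg <- sim_sensorgram_config(ka = 3.64e5, kd = 8e-5, Rmax = 100)
  corrected <- correct_sensorgram(simulate_sensorgram(cfg))
  fit <- fit_full_kinetics(corrected)
  expect_true(fit$converged)
  expect_lt(abs(fit$ka - 3.64e5) / 3.64e5, 1e-6)
  expect_lt(abs(fit$kd - 8e-5) / 8e-5, 1e-6)
  expect_lt(abs(fit$Rmax - 100) / 100, 1e-6)
  expect_equal(fit$KD, fit$kd / fit$ka)        # identity, machine exact
  expect_true(fit$high_significance)

  # dissociation-only kd equals full-fit kd on noiseless data
  off <- fit_dissociation(corrected, Rmax_for_pct = fit$Rmax)
  expect_lt(abs(off$kd - fit$kd) / fit$kd, 1e-9)
})

test_that("KD = kd/ka at the reported antibody on/off rates", {
  cfg <- sim_sensorgram_config(ka = 3.68e5, kd = 4e-4, Rmax = 90)
  fit <- fit_full_kinetics(correct_sensorgram(simulate_sensorgram(cfg)))
  expect_equal(fit$KD, 1.087e-9, tolerance = 1e-3)
})

test_that("response scaling moves Rmax/R0 but not the rate constants", {
  cfg <- sim_sensorgram_config(ka = 2e5, kd = 2e-4, Rmax = 50)
  corrected <- correct_sensorgram(simulate_sensorgram(cfg))
  scaled <- data.table::copy(corrected)
  scaled$response_RU <- scaled$response_RU * 3
  f1 <- fit_full_kinetics(corrected)
  f3 <- fit_full_kinetics(scaled)
  expect_equal(f3$ka, f1$ka, tolerance = 1e-6)
  expect_equal(f3$kd, f1$kd, tolerance = 1e-6)
  expect_equal(f3$Rmax, 3 * f1$Rmax, tolerance = 1e-6)
  expect_equal(unname(f3$R0), 3 * unname(f1$R0), tolerance = 1e-6)
})

test_that("single-concentration series warns about ill-posedness", {
  cfg <- sim_sensorgram_config(ka = 2e5, kd = 2e-4, Rmax = 50,
                               concentrations = 5e-8)
  corrected <- correct_sensorgram(simulate_sensorgram(cfg))
  expect_warning(fit_full_kinetics(corrected), "ill-posed")
})

test_that("model mismatch inflates chi2 percent (2:1 vs 1:1 data)", {
  cfg <- sim_sensorgram_config(ka = 2e5, kd = 2e-4, Rmax = 60)
  good <- correct_sensorgram(simulate_sensorgram(cfg))
  # heterogeneous two-site data: sum of two 1:1 components with very
  # different off-rates, same total Rmax
  hetero <- data.table::copy(good)
  mix <- function(t, C, phase) {
    r1a <- model_association(t, 2e5, 2e-4, C, 30)
    r2a <- model_association(t, 8e5, 8e-3, C, 30)
    if (phase == "assoc") return(r1a + r2a)
    r01 <- model_association(120, 2e5, 2e-4, C, 30)
    r02 <- model_association(120, 8e5, 8e-3, C, 30)
    model_dissociation(t, 2e-4, r01) + model_dissociation(t, 8e-3, r02)
  }
  for (cid in unique(hetero$cycle_id)) {
    for (ph in c("assoc", "dissoc")) {
      i <- hetero$cycle_id == cid & hetero$phase == ph
      hetero$response_RU[i] <- mix(hetero$t_s[i], hetero$conc_M[i][1], ph)
    }
  }
  f_good <- fit_full_kinetics(good)
  f_bad <- fit_full_kinetics(hetero)
  expect_gt(f_bad$chi2_pct, f_good$chi2_pct)
  expect_gt(f_bad$chi2_pct, 100 * f_good$chi2_pct)  # clear separation
})
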