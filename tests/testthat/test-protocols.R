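test_that("single-turnover simulation reproduces the saturating rate", {
  r <- default_rates("crosslinked")
  # no nucleotide, no product
  tc0 <- simulate_single_turnover(r, protocol_config(dNTP_uM = 0,
    quench_times_s = c(0, 0.5, 1, 5)))
  expect_true(all(tc0$signal_nM < 1e-9))
  # saturating dCTP: fitted k_obs within 15% of the configured kp
  fit <- measure_kobs(r, 25)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$k_obs, r$values[["k5"]]), 0.15)
  # signal bounded by the enzyme concentration
  tc <- simulate_single_turnover(r, protocol_config(dNTP_uM = 25))
  expect_true(all(tc$signal_nM <= 30 + 1e-6))
})

test_that("product is limited by whichever of enzyme or nucleotide is scarce", {
  r <- default_rates("crosslinked")
  # 10 nM dNTP against 30 nM enzyme: product can never exceed 10 nM
  tc <- simulate_single_turnover(r, protocol_config(
    dNTP_uM = 0.01, quench_times_s = c(0, 1, 5, 20, 100, 400)))
  expect_true(all(tc$signal_nM <= 10 + 1e-6))
  expect_gt(max(tc$signal_nM), 5) # and most of it is eventually used
})

test_that("pulse-chase signal dominates pulse-quench at every time", {
  r <- default_rates("crosslinked")
  grid <- rfq_time_grid(0.5, 10)
  cfg_q <- protocol_config("pulse_quench", dNTP_uM = 1.5,
                           quench_times_s = grid)
  cfg_c <- protocol_config("pulse_chase", dNTP_uM = 1.5,
                           quench_times_s = grid)
  pq <- simulate_pulse_quench(r, cfg_q)
  pc <- simulate_pulse_chase(r, cfg_c)
  expect_true(all(pc$signal_nM - pq$signal_nM >= -1e-9))
  # quench amplitude is sub-stoichiometric: the pre-chemistry
  # intermediate holds part of the label
  fq <- fit_single_exponential(pq)
  expect_lt(fq$A, 30)
  # and is within ~20% of the binding-equilibrium occupancy scale
  expect_lt(rel_err(fq$A, 30 * 1.5 / (1.5 + 0.38)), 0.2)
})

test_that("a zero-length chase degenerates to the pulse-quench readout", {
  r <- default_rates("crosslinked")
  grid <- rfq_time_grid(0.5, 8)
  pq <- simulate_pulse_quench(r, protocol_config("pulse_quench",
    dNTP_uM = 1.5, quench_times_s = grid))
  pc0 <- simulate_pulse_chase(r, protocol_config("pulse_chase",
    dNTP_uM = 1.5, quench_times_s = grid, chase_duration_s = 0))
  expect_equal(pc0$signal_nM, pq$signal_nM, tolerance = 1e-6)
})

test_that("chase equals quench when no intermediate holds label", {
  # make every pre-chemistry pool transient: instantaneous closing and
  # effectively irreversible fast chemistry
  r <- update_rates(default_rates("crosslinked"),
                    k5 = 1000, k6 = 1000, "k-6" = 0)
  grid <- rfq_time_grid(0.5, 8)
  pq <- simulate_pulse_quench(r, protocol_config("pulse_quench",
    dNTP_uM = 1.5, quench_times_s = grid))
  pc <- simulate_pulse_chase(r, protocol_config("pulse_chase",
    dNTP_uM = 1.5, quench_times_s = grid))
  ratio <- fit_single_exponential(pc)$A / fit_single_exponential(pq)$A
  expect_lt(abs(ratio - 1), 0.02)
})

test_that("quasi-equilibrium limit reproduces the 1 + k-6/k6 amplitude ratio", {
  # reopening much slower than the rearrangement, chase long enough to
  # commit the entire equilibrated pool
  r <- update_rates(default_rates("crosslinked"), "k7" = 0.002)
  grid <- rfq_time_grid(0.45, 12, span_halflives = 10)
  pq <- simulate_pulse_quench(r, protocol_config("pulse_quench",
    dNTP_uM = 1.5, quench_times_s = grid))
  pc <- suppressWarnings(simulate_pulse_chase(r, protocol_config(
    "pulse_chase", dNTP_uM = 1.5, quench_times_s = grid,
    chase_duration_s = 5000)))
  ratio <- fit_single_exponential(pc)$A / fit_single_exponential(pq)$A
  expected <- 1 + r$values[["k-6"]] / r$values[["k6"]]
  expect_lt(rel_err(ratio, expected), 0.05)
})

test_that("elemental substitution only slows the chemistry step", {
  r <- default_rates("crosslinked")
  expect_equal(apply_elemental_substitution(r, 1)$values, r$values)
  expect_error(apply_elemental_substitution(r, 0.5), ">= 1")
  r50 <- apply_elemental_substitution(r, 50)
  expect_equal(r50$values[["k6"]], r$values[["k6"]] / 50)
  expect_equal(r50$values[["k-6"]], r$values[["k-6"]] / 50)
  unchanged <- setdiff(names(r$values), c("k6", "k-6"))
  expect_equal(r50$values[unchanged], r$values[unchanged])
})

test_that("the simulated elemental effect reports the rate-limiting step", {
  r <- default_rates("crosslinked")
  k_O <- measure_kobs(r)$k_obs
  # defaults: rearrangement-limited, so a 50-fold chemistry slowdown
  # barely shows
  k_S <- measure_kobs(apply_elemental_substitution(r, 50))$k_obs
  expect_lt(k_O / k_S, 10)
  expect_gte(k_O / k_S, 1)
  # chemistry-limited configuration: the full factor is expressed
  r_chem <- update_rates(r, k6 = 0.01 * r$values[["k5"]],
                         "k-6" = 0.005 * r$values[["k5"]])
  k_cO <- measure_kobs(r_chem)$k_obs
  k_cS <- measure_kobs(apply_elemental_substitution(r_chem, 50))$k_obs
  expect_lt(rel_err(k_cO / k_cS, 50), 0.15)
  # substitution never speeds the observed rate
  expect_lte(k_S, k_O * (1 + 1e-9))
  expect_lte(k_cS, k_cO * (1 + 1e-9))
})

test_that("temperature scaling follows transition-state theory", {
  r <- default_rates("crosslinked")
  act <- list(k5 = c(dH = 21.5, dS = 11.5))
  # bare prefactor when both activation parameters vanish
  r0 <- apply_temperature(r, 300, list(k5 = c(dH = 0, dS = 0)))
  expect_equal(r0$values[["k5"]], tst_constants$kB_over_h * 300,
               tolerance = 1e-12)
  # only designated rates change
  rT <- apply_temperature(r, 303.15, act)
  same <- setdiff(names(r$values), "k5")
  expect_equal(rT$values[same], r$values[same])
  # k at 37 C is consistent with dG via k = (kB T/h) exp(-dG/RT)
  T37 <- 310.15
  dG <- 21.5 - T37 * 11.5 / 1000
  k_dG <- tst_constants$kB_over_h * T37 *
    exp(-dG / (tst_constants$R_kcal * T37))
  expect_equal(apply_temperature(r, T37, act)$values[["k5"]], k_dG,
               tolerance = 1e-10)
  # two-point round trip recovers the activation parameters exactly
  T1 <- 293.15; T2 <- 310.15
  k1 <- eyring_rate(21.5, 11.5, T1); k2 <- eyring_rate(21.5, 11.5, T2)
  ft <- fit_eyring(c(T1, T2), c(k1, k2))
  expect_equal(ft$dH_kcal, 21.5, tolerance = 1e-9)
  expect_equal(ft$dS_cal, 11.5, tolerance = 1e-9)
  expect_error(apply_temperature(r, -1, act), "positive")
})

test_that("viscosity slows only diffusion-sensitive steps", {
  r <- default_rates("crosslinked")
  expect_equal(apply_viscosity(r, 1)$values, r$values)
  expect_error(apply_viscosity(r, 0.5), ">= 1")
  r2 <- apply_viscosity(r, 2)
  expect_equal(r2$values[["k4"]], r$values[["k4"]] / 2)
  expect_equal(r2$values[["k5"]], r$values[["k5"]])

  # default assignment: saturating k_obs is flat across a 3-fold range
  etas <- c(1, 2, 3)
  k_eta <- vapply(simulate_viscosity_series(r, etas,
    protocol_config(dNTP_uM = 25)), function(tc)
      fit_single_exponential(tc)$k_obs, numeric(1))
  expect_lt(max(abs(k_eta / k_eta[1] - 1)), 0.05)

  # binding made rate-limiting (with downstream steps committed so the
  # readout tracks binding alone): k_obs scales as 1/viscosity
  r_bind <- update_rates(r, k4 = 0.001, "k-4" = 0.00038, "k-6" = 0)
  k_bind <- vapply(simulate_viscosity_series(r_bind, etas,
    protocol_config(dNTP_uM = 25)), function(tc)
      fit_single_exponential(tc)$k_obs, numeric(1))
  expect_lt(max(abs(k_bind * etas / k_bind[1] - 1)), 0.1)
})

test_that("protocol configuration is validated", {
  expect_error(protocol_config(enzyme_complex_nM = 0), "positive")
  expect_error(protocol_config("pulse_chase", dNTP_uM = 10,
                               chase_dNTP_uM = 5), "at least as concentrated")
  expect_error(protocol_config(quench_times_s = c(-1, 1)), "non-negative")
})
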