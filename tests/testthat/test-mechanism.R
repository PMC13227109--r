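test_that("crosslinked scheme enumerates the expected species and steps", {
  r <- default_rates("crosslinked")
  sc <- build_scheme("crosslinked", r, explicit_step5i = TRUE)
  expect_length(sc$species, 16)
  expect_identical(scheme_steps(sc), 10L)
  expect_false(anyDuplicated(sc$species) > 0)
  # lumping the 5i sub-step removes one closed-ternary species
  expect_length(build_scheme("crosslinked", r)$species, 15)
  # observable sets exist and are species subsets
  for (obs in sc$observables) expect_true(all(obs %in% sc$species))
})

test_that("uncrosslinked scheme has a DNA dissociation step labeled k7", {
  sc <- build_scheme("uncrosslinked", default_rates("uncrosslinked"))
  labels <- vapply(sc$reactions, `[[`, character(1), "label")
  k7 <- sc$reactions[[which(labels == "k7")]]
  expect_true("DNAn1" %in% names(k7$products))
  expect_true("E" %in% names(k7$products))
})

test_that("scheme construction validates rate labels and variants", {
  r <- default_rates("crosslinked")
  incomplete <- rate_set("crosslinked", r$values[names(r$values) != "k6"])
  expect_error(build_scheme("crosslinked", incomplete),
               "missing rate label k6")
  expect_error(build_scheme("uncrosslinked", r), "does not match")
  expect_error(rate_set("crosslinked", c(k1 = -1)), "non-negative")
  expect_error(rate_set("crosslinked", c(bogus = 1)), "unknown rate label")
})

test_that("K_d is the off/on ratio of the nucleotide binding step", {
  r <- default_rates("crosslinked")
  expect_equal(kd_uM(r), r$values[["k-4"]] / r$values[["k4"]])
  expect_equal(kd_uM(r), 0.38, tolerance = 1e-12)
})

test_that("mass-action derivatives follow the rate law with unit conversion", {
  r <- default_rates("crosslinked")
  sc <- build_scheme("crosslinked", r)
  zero <- stats::setNames(numeric(length(sc$species)), sc$species)
  expect_true(all(mass_action_derivative(sc, zero) == 0))

  # single first-order reaction: product release at k10
  st <- zero; st["E.DNAn1"] <- 10
  d <- mass_action_derivative(sc, st)
  expect_equal(unname(d["E.DNAn1"]), -10 * r$values[["k10"]])
  expect_equal(unname(d["DNAn1"]), 10 * r$values[["k10"]])
  expect_equal(unname(d["E"]), 10 * r$values[["k10"]])

  # bimolecular step: 1 uM^-1 s^-1 at 100 nM + 100 nM must give 10 nM/s
  r1 <- update_rates(zero_rates(), k1 = 1)
  sc1 <- build_scheme("crosslinked", r1)
  st <- zero; st[c("E", "DNAn")] <- 100
  d <- mass_action_derivative(sc1, st)
  expect_equal(unname(d["E.DNAn"]), 10)
  expect_equal(unname(d["E"]), -10)

  expect_error(mass_action_derivative(sc, st - 1), "negative concentration")
})

test_that("a frozen system stays at its initial state", {
  sc <- build_scheme("crosslinked", zero_rates())
  traj <- integrate_scheme(sc, c(ExDNAn_B = 30, dNTP = 1000),
                           times = c(0.1, 1, 10))
  expect_true(all(abs(traj$ExDNAn_B - 30) < 1e-8))
  expect_true(all(abs(traj$dNTP - 1000) < 1e-6 * 1000))
})

test_that("integration matches closed forms on small sub-networks", {
  # irreversible first-order decay: E.DNAn1 -> E + DNAn1 at k10 = 1
  sc <- build_scheme("crosslinked", only_rates(k10 = 1))
  t_out <- c(0.25, 0.5, 1, 2, 4)
  traj <- integrate_scheme(sc, c(E.DNAn1 = 1), t_out, rtol = 1e-10, atol = 1e-10)
  expect_equal(traj$E.DNAn1, exp(-t_out), tolerance = 1e-6)
  expect_equal(traj$DNAn1, 1 - exp(-t_out), tolerance = 1e-6)

  # reversible pair A <-> B with kf = 2, kr = 1
  sc2 <- build_scheme("crosslinked", only_rates(k3 = 2, "k-3" = 1))
  keq <- 2
  lam <- 3
  traj2 <- integrate_scheme(sc2, c(ExDNAn_A = 1), c(0.1, 0.5, 1, 20),
                            rtol = 1e-10, atol = 1e-10)
  A_exact <- 1 / 3 + (1 - 1 / 3) * exp(-lam * c(0.1, 0.5, 1, 20))
  expect_equal(traj2$ExDNAn_A, A_exact, tolerance = 1e-6)
  long <- traj2[nrow(traj2), ]
  expect_equal(long$ExDNAn_B / long$ExDNAn_A, keq, tolerance = 1e-4)

  # two-step irreversible chain matches the Bateman solution
  k9 <- 1; k10 <- 0.4
  sc3 <- build_scheme("crosslinked", only_rates(k9 = k9, k10 = k10))
  tt <- c(0.2, 1, 3, 8)
  traj3 <- integrate_scheme(sc3, c(ExDNAn1 = 1), tt, rtol = 1e-10, atol = 1e-10)
  mid_exact <- k9 / (k10 - k9) * (exp(-k9 * tt) - exp(-k10 * tt))
  expect_equal(traj3$E.DNAn1, mid_exact, tolerance = 1e-6)
})

test_that("enzyme and DNA totals are conserved for random rate sets", {
  set.seed(42)
  r0 <- default_rates("crosslinked")
  for (i in 1:5) {
    vals <- r0$values * exp(stats::runif(length(r0$values), -1, 1))
    r <- rate_set("crosslinked", vals)
    sc <- build_scheme("crosslinked", r,
                       explicit_step5i = (i %% 2 == 0))
    init <- c(ExDNAn_A = stats::runif(1, 5, 20),
              ExDNAn_B = stats::runif(1, 5, 20),
              E = stats::runif(1, 0, 5),
              DNAn = stats::runif(1, 0, 5),
              dNTP = stats::runif(1, 100, 5000))
    traj <- integrate_scheme(sc, init, c(0.01, 0.1, 1, 5, 20))
    tot0 <- conserved_totals(sc, stats::setNames(
      c(init, stats::setNames(numeric(length(setdiff(sc$species, names(init)))),
                              setdiff(sc$species, names(init)))),
      c(names(init), setdiff(sc$species, names(init)))))
    for (j in seq_len(nrow(traj))) {
      st <- stats::setNames(as.numeric(traj[j, sc$species]), sc$species)
      tot <- conserved_totals(sc, st)
      expect_equal(unname(tot["enzyme"]), unname(tot0["enzyme"]),
                   tolerance = 1e-6)
      expect_equal(unname(tot["dna"]), unname(tot0["dna"]),
                   tolerance = 1e-6)
    }
  }
})

test_that("solutions are invariant to output-grid refinement", {
  r <- default_rates("crosslinked")
  sc <- build_scheme("crosslinked", r)
  init <- c(ExDNAn_A = 15, ExDNAn_B = 15, dNTP = 25000)
  coarse <- seq(0.2, 4, by = 0.2)
  fine <- seq(0.1, 4, by = 0.1)
  tr_c <- integrate_scheme(sc, init, coarse, rtol = 1e-10, atol = 1e-10)
  tr_f <- integrate_scheme(sc, init, fine, rtol = 1e-10, atol = 1e-10)
  sig_c <- observe(tr_c, sc)$signal_nM
  sig_f <- observe(tr_f, sc)$signal_nM[seq(2, length(fine), by = 2)]
  expect_equal(sig_c, sig_f, tolerance = 1e-6)
})

test_that("deterministic solution matches exact stochastic sampling", {
  # two-reaction first-order chain; molecules evolve independently, so
  # per-molecule event times give exact realizations
  k9 <- 1; k10 <- 0.4
  n_mol <- 50; n_real <- 10000
  t_probe <- c(0.5, 1.5, 4)
  set.seed(7)
  sc <- build_scheme("crosslinked", only_rates(k9 = k9, k10 = k10))
  det <- integrate_scheme(sc, c(ExDNAn1 = n_mol), t_probe)
  t1 <- matrix(stats::rexp(n_mol * n_real, k9), n_real)
  t2 <- t1 + matrix(stats::rexp(n_mol * n_real, k10), n_real)
  for (i in seq_along(t_probe)) {
    done <- rowSums(t2 <= t_probe[i]) # molecules in the final state
    se <- stats::sd(done) / sqrt(n_real)
    expect_lt(abs(mean(done) - det$DNAn1[i]), 3 * se + 1e-9)
  }
})

test_that("observables project trajectories correctly", {
  r <- default_rates("crosslinked")
  sc <- build_scheme("crosslinked", r)
  init <- c(ExDNAn_A = 15, ExDNAn_B = 15, dNTP = 25000)
  traj <- integrate_scheme(sc, init, c(0.1, 0.5, 2, 5))
  # summing every species returns the total material
  all_tc <- observe(traj, sc, sc$species)
  expect_equal(all_tc$signal_nM, rowSums(traj[, sc$species]))
  # empty set gives zero signal
  expect_true(all(observe(traj, sc, character(0))$signal_nM == 0))
  # quench-counted product is monotone non-decreasing for defaults
  prod <- observe(traj, sc, "acid_quench_product")$signal_nM
  expect_true(all(diff(prod) >= -1e-9))
  expect_error(observe(traj, sc, "nonexistent"), "unknown observable")
})
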