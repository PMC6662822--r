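# ITC forward model (displacement bookkeeping) and one-site fitting.

paper_design <- itc_design()  # 950 ul cell, 4 + 12 x 20 ul schedule

test_that("zero enthalpy gives zero heats", {
  sim <- simulate_itc(0.06e-6, dH = 0, design = paper_design)
  expect_true(all(sim$injections$heat_uJ == 0))
})

test_that("tight binding is stoichiometric up to equivalence", {
  dH <- -25
  sim <- simulate_itc(1e-15, dH, design = paper_design)
  q <- sim$injections$heat_uJ
  # pre-equivalence main injection: every injected titrant molecule binds,
  # so its heat is dH x moles injected (20 ul x 40 uM)
  inj_mol <- 20e-6 * paper_design$syringe_conc
  expect_equal(q[2], dH * inj_mol * 1e9, tolerance = 0.01)
  # total heat is bounded by dH x initial ligand moles, shaved only by the
  # unbound ligand displaced from the cell before equivalence
  lig_mol <- paper_design$cell_conc * paper_design$cell_volume_ul * 1e-6
  expect_lt(abs(sum(q)), abs(dH * lig_mol * 1e9))
  expect_gt(abs(sum(q)), 0.90 * abs(dH * lig_mol * 1e9))
  expect_lt(abs(q[length(q)]), abs(q[2]) * 0.05)  # saturated tail
})

test_that("simulated heats match the per-injection bisection oracle", {
  for (pars in list(c(0.06e-6, -25.1, 1), c(0.10e-6, -17.7, 1),
                    c(1e-6, -12, 0.8))) {
    sim <- simulate_itc(pars[1], pars[2], pars[3], paper_design)
    expect_equal(sim$injections$heat_uJ,
                 oracle_itc_heats(pars[1], pars[2], pars[3], paper_design),
                 tolerance = 1e-8)
  }
})

test_that("heat bookkeeping conserves the complex balance", {
  Kd <- 0.06e-6; dH <- -25.1; n <- 1
  sim <- simulate_itc(Kd, dH, n, paper_design)
  V0 <- paper_design$cell_volume_ul * 1e-6
  # recompute final and displaced complex amounts independently
  X <- paper_design$cell_conc; M <- 0; C <- 0; displaced <- 0
  for (v_ul in paper_design$injection_volumes_ul) {
    v <- v_ul * 1e-6; f <- 1 - v / V0
    displaced <- displaced + C * (v / V0) * V0
    X <- X * f; M <- M * f + paper_design$syringe_conc * v / V0
    S <- n * X
    C <- S * bisect_fraction_bound(S, M, Kd)
  }
  total_from_heats <- sum(sim$injections$heat_uJ) / (dH * 1e9)
  expect_equal(total_from_heats, C * V0 + displaced, tolerance = 1e-9)
})

test_that("noiseless titrations are fitted back exactly", {
  sim <- simulate_itc(0.06e-6, -25.1, n = 1, design = paper_design)
  fit <- suppressWarnings(fit_itc(sim))
  expect_equal(fit$Kd, 0.06e-6, tolerance = 1e-6)
  expect_equal(fit$dH, -25.1, tolerance = 1e-6)
  expect_equal(fit$n, 1, tolerance = 1e-6)
  expect_equal(fit$thermo$dG, dG_from_Kd(0.06e-6), tolerance = 1e-6)
})

test_that("two noisy experiments fitted jointly recover the truth in the CI", {
  for (seed in c(1, 5)) {
    exps <- lapply(c(seed, seed + 50), function(s)
      simulate_itc(0.06e-6, -25.1, design = paper_design,
                   noise_sd = 0.02, seed = s))
    fit <- fit_itc(exps)
    expect_gte(0.06e-6, fit$ci_Kd[1]); expect_lte(0.06e-6, fit$ci_Kd[2])
    expect_gte(-25.1, fit$ci_dH[1]); expect_lte(-25.1, fit$ci_dH[2])
  }
})

test_that("round-trip estimation is unbiased across the affinity/enthalpy grid", {
  for (Kd in c(0.03e-6, 0.10e-6)) for (dH in c(-25.1, -17.7)) {
    rel_err <- vapply(1:10, function(s) {
      sim <- simulate_itc(Kd, dH, design = paper_design,
                          noise_sd = 0.02, seed = s)
      suppressWarnings(fit_itc(sim))$Kd / Kd - 1
    }, 0)
    expect_lt(abs(stats::median(rel_err)), 0.05)
  }
})

test_that("poorly shaped titrations trigger the c-value warning", {
  sim <- simulate_itc(1e-3, -20, design = paper_design)  # c = 0.005
  expect_warning(fit_itc(sim), "c-value")
})

test_that("experiments shorter than 8 usable injections are rejected", {
  short <- itc_design(injection_volumes_ul = c(4, rep(20, 6)))
  sim <- simulate_itc(0.06e-6, -25.1, design = short)
  expect_error(fit_itc(sim), "usable")
})
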