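# Single-site mass balance, isotherm fitting, free-energy conversions and
# melting-temperature extraction.

test_that("fraction_bound solves the exact 1:1 mass balance", {
  expect_equal(fraction_bound(2.5e-6, 0, 0.35e-3), 0)
  # weak-binding limit: receptor << Kd, ligand at Kd -> half saturation
  expect_equal(fraction_bound(1e-9, 1e-3, 1e-3), 0.5, tolerance = 1e-4)
  # against the bisection oracle on a 10x10x10 grid
  R0s <- 10^seq(-9, -3, length.out = 10)
  L0s <- 10^seq(-8, -1, length.out = 10)
  Kds <- 10^seq(-9, -1, length.out = 10)
  for (R0 in R0s) for (L0 in L0s) for (Kd in Kds)
    expect_equal(fraction_bound(R0, L0, Kd),
                 bisect_fraction_bound(R0, L0, Kd), tolerance = 1e-10)
})

test_that("fraction_bound is monotone in ligand and in affinity", {
  L <- 10^seq(-7, -1, length.out = 30)
  fb <- fraction_bound(2.5e-6, L, 0.35e-3)
  expect_true(all(diff(fb) > 0))
  Kds <- 10^seq(-6, -2, length.out = 20)
  fb2 <- vapply(Kds, function(k) fraction_bound(2.5e-6, 1e-3, k), 0)
  expect_true(all(diff(fb2) < 0))
})

test_that("free-energy conversion reproduces the published table", {
  # printed-precision checks of the closed form
  expect_equal(dG_from_Kd(0.35e-3), -19.73, tolerance = 0.005 / 19.73)
  expect_lt(abs(dG_from_Kd(96e-9) - (-40.1)), 0.05)
  expect_lt(abs(dG_from_Kd(0.10e-6) - (-40.0)), 0.05)
  expect_equal(dG_from_Kd(1), 0)
  # error propagation: sigma_dG = RT sigma/Kd
  g <- dG_from_Kd(0.35e-3, sigma_Kd = 0.02e-3)
  expect_equal(g$sigma_dG, 8.314 * 298.15 * 0.02 / 0.35 / 1000, tolerance = 1e-9)
})

test_that("whole-table Kd/dG pairs are self-consistent given printed precision", {
  tab <- reference_thermo_table()
  for (i in seq_len(nrow(tab))) {
    # half a unit in the last printed digit of Kd widens the admissible band
    ulp <- 10^(floor(log10(tab$Kd_M[i])) - tab$kd_digits[i] + 1)
    dg_lo <- dG_from_Kd(tab$Kd_M[i] + ulp / 2)
    dg_hi <- dG_from_Kd(tab$Kd_M[i] - ulp / 2)
    round_width <- (dg_hi - dg_lo) / 2
    expect_lt(abs(dG_from_Kd(tab$Kd_M[i]) - tab$dG_kJmol[i]),
              0.06 + abs(round_width))
  }
  # all multi-digit entries already meet the plain band
  multi <- tab[tab$kd_digits >= 2, ]
  expect_true(all(abs(dG_from_Kd(multi$Kd_M) - multi$dG_kJmol) <= 0.06))
})

test_that("dG and Kd conversions are mutual inverses", {
  Kds <- 10^seq(-12, 0, length.out = 40)
  expect_equal(Kd_from_dG(dG_from_Kd(Kds)), Kds, tolerance = 1e-12)
  dGs <- seq(-60, 0, length.out = 40)
  expect_equal(dG_from_Kd(Kd_from_dG(dGs)), dGs, tolerance = 1e-12)
})

test_that("entropy follows from enthalpy and free energy with propagated error", {
  expect_equal(dS_from_dG_dH(-20, -20), 0)
  # closed-form values sit inside the printed ITC entropy bands
  s1 <- dS_from_dG_dH(-40.0, -17.7)
  expect_equal(s1, 74.79457, tolerance = 1e-6)
  expect_lt(abs(s1 - 70), 11)
  s2 <- dS_from_dG_dH(-41.3, -25.1)
  expect_equal(s2, 54.33507, tolerance = 1e-6)
  expect_lt(abs(s2 - 47), 8)
  p <- dS_from_dG_dH(-41.3, -25.1, sigma_dG = 1.1, sigma_dH = 1.2)
  expect_equal(p$sigma_dS, sqrt(1.1^2 + 1.2^2) * 1000 / 298.15, tolerance = 1e-9)
})

test_that("thermo_state bundles a consistent Kd/dG/dH/dS set", {
  st <- thermo_state(0.06e-6, 0.03e-6, dH = -25.1, sigma_dH = 1.2)
  expect_equal(st$dG, dG_from_Kd(0.06e-6))
  expect_equal(st$dS, (st$dH - st$dG) * 1000 / st$T_K)
})

test_that("noiseless isotherms are recovered exactly", {
  conc <- 10^seq(-7, -2, length.out = 16)
  d <- simulate_titration(0.39e-3, 5e-8, conc, replicates = 1, noise_sd = 0)
  fit <- fit_isotherm(d, receptor_total = 5e-8)
  expect_equal(fit$Kd, 0.39e-3, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("replicated noisy pseudo-titrations recover the lead-peptide Kd", {
  for (seed in c(3, 12)) {
    d <- generate_scenario("mst_keseee", seed = seed)
    fit <- fit_isotherm(d$data, d$truth$receptor_total)
    expect_gte(0.39e-3, fit$ci_Kd[1])
    expect_lte(0.39e-3, fit$ci_Kd[2])
  }
  # the reference substrate decapeptide binds visibly weaker
  lead <- fit_isotherm(generate_scenario("mst_keseee", seed = 6)$data, 5e-8)
  ref <- fit_isotherm(generate_scenario("mst_rrrdddsddd", seed = 6)$data, 5e-8)
  expect_gt(ref$Kd, lead$Kd)
})

test_that("a high-concentration cutoff excludes unfolding-distorted points", {
  d <- generate_scenario("mst_keseee", seed = 8)
  fit <- fit_isotherm(d$data, d$truth$receptor_total, conc_max = 1e-3)
  expect_true(all(is.finite(fit$ci_Kd)))
  expect_equal(fit$conc_max, 1e-3)
  expect_lt(fit$n_obs, nrow(d$data))
})

test_that("native and unfolded protein slices give distinct affinities", {
  conc <- 10^seq(log10(3e-7), -2, length.out = 16)
  native <- simulate_titration(0.35e-3, 2.5e-6, conc, S_free = 0.80,
                               S_bound = 0.74, replicates = 2,
                               noise_sd = 0.01, seed = 21)
  unfolded <- simulate_titration(1e-3, 2.5e-6, conc, S_free = 0.95,
                                 S_bound = 0.90, replicates = 2,
                                 noise_sd = 0.01, seed = 22)
  f_n <- fit_isotherm(native, 2.5e-6)
  f_u <- fit_isotherm(unfolded, 2.5e-6)
  expect_gt(f_u$Kd, f_n$Kd)
  expect_gt(f_u$ci_Kd[1], f_n$ci_Kd[2])  # separated at 95% confidence
})

test_that("melting temperature is read off the derivative extremum", {
  d <- generate_scenario("dsf_melt", seed = 2)
  tm <- extract_tm(d$data)
  expect_equal(tm$Tm, 45, tolerance = 0.2 / 45)
  # noiseless symmetric sigmoid: Tm equals the inflection midpoint
  clean <- simulate_melting_curve(Tm_C = 52, noise_sd = 0)
  expect_equal(extract_tm(clean)$Tm, 52, tolerance = 1e-2)
})

test_that("peptide binding depresses the apparent melting temperature", {
  d <- generate_scenario("dsf_melt_series", seed = 3)
  concs <- sort(unique(d$data$conc_M))
  tms <- vapply(concs, function(cc)
    extract_tm(d$data[d$data$conc_M == cc, ])$Tm, 0)
  expect_true(all(diff(tms) <= 0.1))        # monotone decrease (noise slack)
  expect_lt(tms[length(tms)], tms[1] - 3)   # near-saturating depression
})

test_that("flat curves raise a no-transition error", {
  flat <- data.frame(temp_C = seq(20, 80, 0.5), ratio = 0.8)
  expect_error(extract_tm(flat), class = "peptherm_no_transition")
})
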