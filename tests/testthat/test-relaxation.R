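# Bi-exponential decay simulation, global fitting and affinity ranking.

test_that("simulated decay follows the bi-exponential forward model", {
  # mono-exponential limit at t = 0
  s <- simulate_decay(biexp_params(A1 = 0, A2 = 1, R2f = 10, R2s = 2.5),
                      delays = c(0, 0.05, 0.4, 0.8, 1.5, 3))
  expect_equal(s$intensity[1], 1)
  # long-delay asymptote is the offset
  s2 <- simulate_decay(biexp_params(1, 1, 31.3, 2.5, y0 = 0.25),
                       delays = c(0, 0.1, 0.2, 5, 10, 50))
  expect_equal(s2$intensity[s2$delay_s == 50], 0.25, tolerance = 1e-6)
  # lead-peptide rates at t = 0.1 s: frozen hand evaluation of the model
  s3 <- simulate_decay(biexp_params(1, 1, 31.3, 2.5))
  expect_equal(s3$intensity[s3$delay_s == 0.1], 0.8225186, tolerance = 1e-6)
  expect_error(simulate_decay(biexp_params(1, 1, -3, 1)), "non-negative")
  expect_error(simulate_decay(biexp_params(1, 1, 3, 1), noise_sd = -0.1))
})

test_that("noiseless data are recovered to numerical precision", {
  truth <- list(biexp_params(A1 = 0.9, A2 = 1.1, R2f = 31.3, R2s = 2.5),
                biexp_params(A1 = 0.5, A2 = 1.5, R2f = 31.3, R2s = 2.5))
  fit <- fit_biexp_global(simulate_decay(truth))
  expect_equal(fit$R2f, 31.3, tolerance = 1e-6)
  expect_equal(fit$R2s, 2.5, tolerance = 1e-6)
  expect_equal(fit$regions$A1, c(0.9, 0.5), tolerance = 1e-6)
  expect_equal(fit$regions$A2, c(1.1, 1.5), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("a pure mono-exponential is recognised as the degenerate sub-model", {
  fit <- fit_biexp_global(simulate_decay(biexp_params(0, 1.3, 40, 2.5)))
  expect_equal(fit$R2s, 2.5, tolerance = 1e-4)
  expect_lt(fit$regions$A1[1], 1e-6)
})

test_that("component exchange leaves the curve unchanged and the fit canonical", {
  a <- simulate_decay(biexp_params(A1 = 0.7, A2 = 1.2, R2f = 25, R2s = 3))
  b <- simulate_decay(biexp_params(A1 = 1.2, A2 = 0.7, R2f = 3, R2s = 25))
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  fit <- fit_biexp_global(a)
  expect_gte(fit$R2f, fit$R2s)
})

test_that("published-rate synthetic decays are recovered within the 95% CI", {
  for (seed in c(2, 9)) {
    d <- generate_scenario("nmr_keseee", seed = seed)
    fit <- fit_biexp_global(d$data)
    expect_gte(31.3, fit$ci_R2f[1])
    expect_lte(31.3, fit$ci_R2f[2])
  }
  # the weak aspartate-rich binder relaxes visibly slower than the lead
  f_weak <- fit_biexp_global(generate_scenario("nmr_ddtddd", seed = 4)$data)
  f_lead <- fit_biexp_global(generate_scenario("nmr_keseee", seed = 4)$data)
  expect_lt(f_weak$R2f, f_lead$R2f)
})

test_that("larger true fast rates give larger fitted fast rates on average", {
  mean_fit <- function(r2f) {
    mean(vapply(1:6, function(s) {
      sim <- simulate_decay(
        list(biexp_params(1, 1, r2f, 2.5), biexp_params(0.8, 1.2, r2f, 2.5)),
        noise_sd = 0.02, seed = s)
      fit_biexp_global(sim)$R2f
    }, 0))
  }
  fits <- vapply(c(10, 20, 31.3), mean_fit, 0)
  expect_true(all(diff(fits) > 0))
})

test_that("ranking orders by fast rate with ratio tie-break", {
  rk <- rank_peptides(reference_relaxation_rates())
  expect_equal(rk$peptide[1], "KESEEE")
  expect_equal(rk$peptide[nrow(rk)], "DDTDDD")
  single <- rank_peptides(data.frame(peptide = "KESEEE", R2f = 31.3, R2s = 2.5))
  expect_equal(single$peptide, "KESEEE")
  # tie on R2f resolved by R2f/R2s
  tie <- rank_peptides(data.frame(peptide = c("a", "b"), R2f = c(10, 10),
                                  R2s = c(2, 1)))
  expect_equal(tie$peptide, c("b", "a"))
})

test_that("underdetermined designs are rejected", {
  short <- simulate_decay(biexp_params(1, 1, 30, 2), delays = c(0, 0.01, 0.05, 0.1, 0.2))
  expect_error(fit_biexp_global(short), "delays")
})
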