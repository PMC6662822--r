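# Isothermal titration calorimetry: forward simulation and one-site fitting
# of the reverse-titration design (ligand in the cell, protein in the
# syringe) with perfusion-cell displacement bookkeeping.

#' ITC experimental design
#'
#' The instrument schedule: a fixed-volume cell initially filled with the
#' ATP-site ligand, titrated by protein from the syringe with a small
#' discardable pre-injection followed by equal main injections.
#'
#' @param cell_volume_ul Active cell volume, microlitres.
#' @param cell_conc Concentration of the species initially in the cell, M.
#' @param syringe_conc Titrant concentration in the syringe, M.
#' @param injection_volumes_ul Per-injection volumes, microlitres; the first
#'   entry is treated as the pre-injection and excluded from fitting.
#' @param T_K Temperature, K.
#' @return List of class `"itc_design"`.
#' @examples
#' itc_design()  # 4 ul pre-injection + 12 x 20 ul into a 950 ul cell
#' @export
itc_design <- function(cell_volume_ul = 950, cell_conc = 5e-6,
                       syringe_conc = 40e-6,
                       injection_volumes_ul = c(4, rep(20, 12)),
                       T_K = 298.15) {
  if (any(injection_volumes_ul <= 0) || cell_volume_ul <= 0)
    stop("volumes must be positive")
  stopifnot_scalar_pos(cell_conc, "cell_conc")
  stopifnot_scalar_pos(syringe_conc, "syringe_conc")
  structure(list(cell_volume_ul = cell_volume_ul, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes_ul = injection_volumes_ul, T_K = T_K),
            class = "itc_design")
}

# Complex concentration (M) at 1:1 equilibrium between site concentration
# `s` and titrant concentration `m`.
.complex_conc <- function(s, m, Kd) {
  b <- s + m + Kd
  2 * s * m / (b + sqrt(pmax(b^2 - 4 * s * m, 0)))
}

# Per-injection heats (uJ) of the one-site model under the displacement
# convention: each injection expels `v` of pre-injection cell content, then
# the injected titrant mixes in; heats track the change in complex *in the
# active volume*, including complex lost to the overflow.
.itc_forward <- function(Kd, dH, n, design, Q0 = 0) {
  V0 <- design$cell_volume_ul * 1e-6          # L
  X <- design$cell_conc                        # cell species conc, M
  M <- 0                                       # titrant conc, M
  C_prev <- 0                                  # complex conc, M
  heats <- numeric(length(design$injection_volumes_ul))
  for (i in seq_along(heats)) {
    v <- design$injection_volumes_ul[i] * 1e-6
    f <- 1 - v / V0
    X <- X * f
    M <- M * f + design$syringe_conc * v / V0
    C_new <- .complex_conc(n * X, M, Kd)
    # dH kJ/mol * mol -> kJ; *1e9 -> uJ
    heats[i] <- dH * (C_new - C_prev * f) * V0 * 1e9 + Q0
    C_prev <- C_new
  }
  heats
}

#' Simulate an ITC titration
#'
#' Generates per-injection integrated heats for a 1:1 one-site binding
#' model on the given design, with additive Gaussian noise scaled to the
#' largest clean heat. Stoichiometry `n` multiplies the cell-species
#' concentration (apparent sites per molecule in the cell).
#'
#' @param Kd Dissociation constant, M.
#' @param dH Binding enthalpy, kJ/mol.
#' @param n Apparent stoichiometry (> 0).
#' @param design An [itc_design()].
#' @param noise_sd Fractional noise (of the maximum absolute heat).
#' @param seed Optional integer seed.
#' @return Object of class `"itc_experiment"`: the design plus
#'   `injection_ul`, `heat_uJ` and a logical `pre_injection` marker, as a
#'   data frame in `$injections`.
#' @examples
#' sim <- simulate_itc(0.06e-6, -25.1, design = itc_design(), seed = 1)
#' @export
simulate_itc <- function(Kd, dH, n = 1, design = itc_design(),
                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(design, "itc_design"))
  stopifnot_scalar_pos(Kd, "Kd"); stopifnot_scalar_pos(n, "n")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  clean <- .itc_forward(Kd, dH, n, design)
  heats <- with_seed(seed, {
    sd_abs <- noise_sd * max(abs(clean), .Machine$double.eps)
    clean + stats::rnorm(length(clean), 0, if (noise_sd > 0) sd_abs else 0)
  })
  inj <- data.frame(
    injection_ul = design$injection_volumes_ul,
    heat_uJ = heats,
    pre_injection = seq_along(heats) == 1L
  )
  structure(c(design, list(injections = inj,
                           truth = list(Kd = Kd, dH = dH, n = n))),
            class = "itc_experiment")
}

#' Build an ITC experiment from measured heats
#'
#' @param heats_uJ Integrated heats per injection, microjoules, in
#'   injection order (pre-injection first).
#' @param design An [itc_design()] whose schedule matches `heats_uJ`.
#' @return An `"itc_experiment"` object.
#' @export
itc_experiment <- function(heats_uJ, design = itc_design()) {
  if (length(heats_uJ) != length(design$injection_volumes_ul))
    stop("number of heats must match the injection schedule")
  structure(c(design, list(
    injections = data.frame(injection_ul = design$injection_volumes_ul,
                            heat_uJ = heats_uJ,
                            pre_injection = seq_along(heats_uJ) == 1L),
    truth = NULL)), class = "itc_experiment")
}

#' Fit the one-site ITC model
#'
#' Least-squares fit of per-injection heats to the one-site 1:1 model with
#' parameters Kd (fitted on the log scale), dH, apparent stoichiometry n and
#' a constant baseline heat per injection. The pre-injection is excluded
#' from the residuals but retained in the concentration bookkeeping.
#' Several experiments (e.g. repeat titrations at different concentrations)
#' can be fitted jointly with all parameters shared. A Wiseman c-value
#' (cell concentration / Kd) outside \[1, 1000\] triggers a warning that Kd
#' is poorly determined by the curve shape.
#'
#' @param experiments An `"itc_experiment"` or list of them.
#' @param Kd_bounds Search bounds for Kd, M.
#' @return Object of class `"itc_fit"`: `Kd`, `sigma_Kd`, `ci_Kd`, `dH`,
#'   `sigma_dH`, `n`, `baseline_uJ`, the parameter table, a
#'   [thermo_state()] in `$thermo`, and `c_value`.
#' @examples
#' sim <- simulate_itc(0.06e-6, -25.1, design = itc_design(),
#'                     noise_sd = 0.02, seed = 1)
#' fit <- fit_itc(sim)
#' fit$Kd
#' @export
fit_itc <- function(experiments, Kd_bounds = c(1e-12, 1e-3)) {
  if (inherits(experiments, "itc_experiment")) experiments <- list(experiments)
  stopifnot(all(vapply(experiments, inherits, TRUE, "itc_experiment")))
  usable <- vapply(experiments, function(e) sum(!e$injections$pre_injection),
                   integer(1))
  if (any(usable < 8))
    stop("need at least 8 usable (non-pre) injections per experiment")

  obs <- lapply(experiments, function(e)
    e$injections$heat_uJ[!e$injections$pre_injection])
  resid_fn <- function(p) {
    unlist(Map(function(e, y) {
      pred <- .itc_forward(exp(p[["lkd"]]), p[["dh"]], p[["n"]], e,
                           Q0 = p[["q0"]])
      y - pred[!e$injections$pre_injection]
    }, experiments, obs), use.names = FALSE)
  }
  tot_heat <- sum(vapply(obs, sum, 0))
  dh0 <- if (tot_heat < 0) -20 else 20
  starts <- lapply(exp(seq(log(1e-9), log(1e-4), length.out = 5)), function(k)
    list(lkd = log(k), dh = dh0, n = 1, q0 = 0))
  fit <- multistart_nlslm(
    resid_fn, starts,
    lower = c(log(Kd_bounds[1]), -Inf, 1e-3, -Inf),
    upper = c(log(Kd_bounds[2]), Inf, 100, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000,
                                         ftol = 1e-15, ptol = 1e-15))
  df <- sum(usable) - length(fit$par)
  ptab <- nlslm_param_table(fit, df)
  g <- function(nm) match(nm, ptab$parameter)
  Kd <- exp(ptab$estimate[g("lkd")])
  c_val <- mean(vapply(experiments, function(e) e$cell_conc, 0)) / Kd
  if (!is.finite(c_val) || c_val < 1 || c_val > 1000)
    warning(sprintf(
      "Wiseman c-value %.3g outside [1, 1000]: Kd poorly determined", c_val))
  T_K <- experiments[[1]]$T_K
  st <- thermo_state(Kd, Kd * ptab$se[g("lkd")],
                     dH = ptab$estimate[g("dh")],
                     sigma_dH = ptab$se[g("dh")], T_K = T_K)
  structure(list(
    Kd = Kd, sigma_Kd = Kd * ptab$se[g("lkd")],
    ci_Kd = exp(c(ptab$ci_lo[g("lkd")], ptab$ci_hi[g("lkd")])),
    dH = ptab$estimate[g("dh")], sigma_dH = ptab$se[g("dh")],
    ci_dH = c(ptab$ci_lo[g("dh")], ptab$ci_hi[g("dh")]),
    n = ptab$estimate[g("n")], sigma_n = ptab$se[g("n")],
    baseline_uJ = ptab$estimate[g("q0")],
    parameters = ptab, thermo = st, c_value = c_val,
    converged = fit$info %in% 1:4, deviance = fit$deviance,
    n_experiments = length(experiments)
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("One-site ITC fit (%d experiment%s)\n", x$n_experiments,
              if (x$n_experiments > 1) "s" else ""))
  cat(sprintf("  Kd = %.3g +/- %.2g M;  dH = %.1f +/- %.1f kJ/mol;  n = %.2f\n",
              x$Kd, x$sigma_Kd, x$dH, x$sigma_dH, x$n))
  cat(sprintf("  dG = %.1f kJ/mol;  dS = %.1f J/mol/K;  c = %.3g\n",
              x$thermo$dG, x$thermo$dS, x$c_value))
  invisible(x)
}
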