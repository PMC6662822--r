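# Single-site binding: exact 1:1 mass-balance, isotherm fitting for
# nanoDSF/MST titrations, and Kd <-> free-energy conversions with error
# propagation.

#' Fraction of receptor bound at 1:1 equilibrium
#'
#' Exact solution of the single-site mass balance. With total receptor R0,
#' total ligand L0 and dissociation constant Kd, the complex concentration is
#' the smaller root of `RL^2 - (R0+L0+Kd)RL + R0*L0 = 0`, and the bound
#' fraction is `RL/R0`. No free-ligand approximation is made, so the
#' expression is valid even when receptor and Kd are comparable.
#'
#' @param receptor_total Total receptor concentration, M (>= 0).
#' @param ligand_total Total ligand concentration, M (>= 0); vectorised.
#' @param Kd Dissociation constant, M (> 0).
#' @return Bound fraction in \[0, 1\].
#' @examples
#' fraction_bound(2.5e-6, 1e-3, 0.35e-3)
#' @export
fraction_bound <- function(receptor_total, ligand_total, Kd) {
  stopifnot_scalar_pos(Kd, "Kd")
  if (any(receptor_total < 0) || any(ligand_total < 0))
    stop("total concentrations must be >= 0")
  if (receptor_total == 0) return(rep(0, length(ligand_total)))
  b <- receptor_total + ligand_total + Kd
  # numerically stable smaller root of the mass-balance quadratic
  rl <- 2 * receptor_total * ligand_total /
    (b + sqrt(pmax(b^2 - 4 * receptor_total * ligand_total, 0)))
  pmin(pmax(rl / receptor_total, 0), 1)
}

#' Fit a single-site binding isotherm
#'
#' Least-squares fit of `S(L) = S_free + (S_bound - S_free) * fb(R0, L, Kd)`
#' to a titration (nanoDSF fluorescence-ratio slice or MST thermophoresis
#' amplitude). The dissociation constant is fitted on the log scale with
#' seeded multi-start initialisation; replicate series are fitted globally
#' with Kd and amplitude shared and, optionally, a free baseline per
#' replicate (instrument-to-instrument jitter in MST runs).
#'
#' @param data Data frame with columns `conc_M`, `signal`, and optionally
#'   `replicate`.
#' @param receptor_total Fixed receptor (labelled species) concentration, M.
#' @param per_replicate_baseline Fit a separate free-state baseline per
#'   replicate (default `TRUE` when more than one replicate is present).
#' @param conc_max Optional upper concentration cutoff, M: points above it
#'   are excluded before fitting (e.g. where ~1 mM peptide unfolds the
#'   protein and distorts the MST signal); the cutoff is recorded on the fit.
#' @param Kd_bounds Search bounds for Kd, M.
#' @return Object of class `"binding_fit"`: `Kd`, `sigma_Kd`, `ci_Kd`
#'   (95%), `S_free` (per replicate), `S_bound`, amplitude, parameter table,
#'   `converged`, and fit metadata.
#' @examples
#' d <- generate_scenario("mst_keseee", seed = 1)
#' fit <- fit_isotherm(d$data, receptor_total = d$truth$receptor_total)
#' fit$Kd
#' @export
fit_isotherm <- function(data, receptor_total,
                         per_replicate_baseline = NULL,
                         conc_max = NULL,
                         Kd_bounds = c(1e-12, 1)) {
  stopifnot(all(c("conc_M", "signal") %in% names(data)))
  stopifnot_scalar_pos(receptor_total, "receptor_total")
  if (!is.null(conc_max)) data <- data[data$conc_M <= conc_max, , drop = FALSE]
  if (any(data$conc_M < 0)) stop("concentrations must be >= 0")
  if (nrow(data) < 4) stop("too few titration points to fit")
  rep_id <- if ("replicate" %in% names(data)) factor(data$replicate)
            else factor(rep(1, nrow(data)))
  nrep <- nlevels(rep_id)
  per_replicate_baseline <- per_replicate_baseline %||% (nrep > 1)
  nbase <- if (per_replicate_baseline) nrep else 1
  base_idx <- if (per_replicate_baseline) as.integer(rep_id) else rep(1L, nrow(data))

  amp0 <- diff(range(tapply(data$signal, data$conc_M, mean)))
  lo_sig <- mean(data$signal[data$conc_M <= stats::quantile(data$conc_M, 0.2)])
  hi_sig <- mean(data$signal[data$conc_M >= stats::quantile(data$conc_M, 0.8)])
  sign_amp <- if (hi_sig >= lo_sig) 1 else -1

  resid_fn <- function(p) {
    fb <- fraction_bound(receptor_total, data$conc_M, exp(p[["lkd"]]))
    pred <- unlist(p[paste0("b", base_idx)]) + p[["amp"]] * fb
    data$signal - pred
  }
  pos <- data$conc_M[data$conc_M > 0]
  start_kds <- exp(seq(log(max(min(pos), Kd_bounds[1])),
                       log(min(max(pos), Kd_bounds[2])), length.out = 5))
  starts <- lapply(start_kds, function(k) {
    st <- list(lkd = log(k), amp = sign_amp * max(abs(amp0), 1e-12))
    for (j in seq_len(nbase)) st[[paste0("b", j)]] <- lo_sig
    st
  })
  lower <- c(log(Kd_bounds[1]), -Inf, rep(-Inf, nbase))
  upper <- c(log(Kd_bounds[2]), Inf, rep(Inf, nbase))
  fit <- multistart_nlslm(resid_fn, starts, lower, upper,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  df <- nrow(data) - length(fit$par)
  ptab <- nlslm_param_table(fit, df)
  i <- match("lkd", ptab$parameter)
  Kd <- exp(ptab$estimate[i])
  se_l <- ptab$se[i]
  at_bound <- Kd <= Kd_bounds[1] * 1.01 || Kd >= Kd_bounds[2] * 0.99
  structure(list(
    Kd = Kd, sigma_Kd = Kd * se_l,
    ci_Kd = exp(c(ptab$ci_lo[i], ptab$ci_hi[i])),
    amplitude = ptab$estimate[match("amp", ptab$parameter)],
    S_free = ptab$estimate[grep("^b", ptab$parameter)],
    S_bound = ptab$estimate[grep("^b", ptab$parameter)] +
      ptab$estimate[match("amp", ptab$parameter)],
    parameters = ptab, receptor_total = receptor_total,
    conc_max = conc_max, n_obs = nrow(data), n_replicates = nrep,
    converged = fit$info %in% 1:4 && !at_bound, at_bound = at_bound,
    deviance = fit$deviance, model = "single-site"
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Single-site binding fit (%d points, %d replicate%s)\n",
              x$n_obs, x$n_replicates, if (x$n_replicates > 1) "s" else ""))
  cat(sprintf("  Kd = %.3g +/- %.2g M  [95%% CI %.3g, %.3g]\n",
              x$Kd, x$sigma_Kd, x$ci_Kd[1], x$ci_Kd[2]))
  cat(sprintf("  dG = %.2f kJ/mol at 298.15 K;  converged: %s\n",
              dG_from_Kd(x$Kd), x$converged))
  invisible(x)
}

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(Kd / 1 M)` with `R = 8.314 J/(mol K)`, reported in kJ/mol
#' (negative for sub-molar Kd). The uncertainty, when a `sigma_Kd` is given,
#' propagates as `sigma_dG = R T sigma_Kd / Kd`.
#'
#' @param Kd Dissociation constant(s), M.
#' @param T_K Temperature, K (default 298.15, i.e. 25 degC).
#' @param sigma_Kd Optional standard error(s) of Kd, M.
#' @return Numeric dG in kJ/mol, or a data frame `dG`, `sigma_dG` when
#'   `sigma_Kd` is supplied.
#' @examples
#' dG_from_Kd(0.35e-3)  # -19.73 kJ/mol
#' @export
dG_from_Kd <- function(Kd, T_K = 298.15, sigma_Kd = NULL) {
  if (any(Kd <= 0)) stop("'Kd' must be > 0")
  dG <- GAS_CONSTANT * T_K * log(Kd) / 1000
  if (is.null(sigma_Kd)) return(dG)
  data.frame(dG = dG, sigma_dG = GAS_CONSTANT * T_K * (sigma_Kd / Kd) / 1000)
}

#' @rdname dG_from_Kd
#' @param dG Binding free energy, kJ/mol.
#' @export
Kd_from_dG <- function(dG, T_K = 298.15) {
  exp(dG * 1000 / (GAS_CONSTANT * T_K))
}

#' Binding entropy from free energy and enthalpy
#'
#' `dS = (dH - dG) / T`, in J/(mol K); uncertainties add in quadrature over
#' the independent dG and dH errors.
#'
#' @param dG,dH kJ/mol.
#' @param T_K Temperature, K.
#' @param sigma_dG,sigma_dH Optional standard errors, kJ/mol.
#' @return dS in J/(mol K), or a data frame `dS`, `sigma_dS`.
#' @examples
#' dS_from_dG_dH(-40.0, -17.7)  # ~74.8 J/mol/K
#' @export
dS_from_dG_dH <- function(dG, dH, T_K = 298.15,
                          sigma_dG = NULL, sigma_dH = NULL) {
  if (any(T_K <= 0)) stop("'T_K' must be > 0")
  dS <- (dH - dG) * 1000 / T_K
  if (is.null(sigma_dG) && is.null(sigma_dH)) return(dS)
  sG <- sigma_dG %||% 0; sH <- sigma_dH %||% 0
  data.frame(dS = dS, sigma_dS = sqrt(sG^2 + sH^2) * 1000 / T_K)
}

#' Full thermodynamic state from Kd and enthalpy
#'
#' Bundles `Kd`, `dG = RT ln Kd`, `dH` and `dS = (dH - dG)/T` with
#' propagated uncertainties at temperature `T_K`.
#'
#' @param Kd Dissociation constant, M.
#' @param sigma_Kd Standard error of Kd, M.
#' @param dH Binding enthalpy, kJ/mol (optional).
#' @param sigma_dH Standard error of dH, kJ/mol.
#' @param T_K Temperature, K.
#' @return List of class `"thermo_state"`.
#' @export
thermo_state <- function(Kd, sigma_Kd = 0, dH = NA_real_, sigma_dH = 0,
                         T_K = 298.15) {
  g <- dG_from_Kd(Kd, T_K, sigma_Kd)
  out <- list(Kd = Kd, sigma_Kd = sigma_Kd, dG = g$dG, sigma_dG = g$sigma_dG,
              dH = dH, sigma_dH = sigma_dH, T_K = T_K,
              dS = NA_real_, sigma_dS = NA_real_)
  if (!is.na(dH)) {
    s <- dS_from_dG_dH(g$dG, dH, T_K, g$sigma_dG, sigma_dH)
    out$dS <- s$dS; out$sigma_dS <- s$sigma_dS
  }
  structure(out, class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("Kd = %.3g +/- %.2g M;  dG = %.2f +/- %.2f kJ/mol (T = %.2f K)\n",
              x$Kd, x$sigma_Kd, x$dG, x$sigma_dG, x$T_K))
  if (!is.na(x$dH))
    cat(sprintf("dH = %.1f +/- %.1f kJ/mol;  dS = %.1f +/- %.1f J/mol/K\n",
                x$dH, x$sigma_dH, x$dS, x$sigma_dS))
  invisible(x)
}

#' Published binding thermodynamics table
#'
#' The printed dissociation constants and binding free energies (plus ITC
#' enthalpies/entropies) for the peptide and ATP-site ligand titrations of
#' the CK2 catalytic subunit, by assay and titrate (apo protein or a
#' preformed binary complex). `kd_digits` records the number of significant
#' figures the Kd was printed with, which bounds the rounding-induced
#' uncertainty of any quantity recomputed from it.
#'
#' @return Data frame with columns `assay`, `titrate`, `titrant`, `Kd_M`,
#'   `sigma_Kd_M`, `kd_digits`, `dG_kJmol`, `sigma_dG_kJmol`, `dH_kJmol`,
#'   `sigma_dH_kJmol`, `dS_JmolK`, `sigma_dS_JmolK`.
#' @export
reference_thermo_table <- function() {
  data.frame(
    assay = c(rep("nanoDSF", 5), rep("MST", 5), rep("ITC", 2)),
    titrate = c(rep("hCK2a", 4), "hCK2a+TBBt",
                "hCK2a", "hCK2a", "hCK2a", "hCK2a+KESEEE", "hCK2a+TBBt",
                "TBBt", "TBBt"),
    titrant = c("KESEEE", "EESEEE", "KETEEE", "EETEEE", "KESEEE",
                "KESEEE", "RRRDDDSDDD", "TBBt", "TBBt", "KESEEE",
                "hCK2a", "hCK2a+KESEEE"),
    Kd_M = c(0.35e-3, 1.58e-3, 0.95e-3, 0.96e-3, 0.45e-3,
             0.39e-3, 2.1e-3, 96e-9, 86e-9, 0.36e-3,
             0.06e-6, 0.10e-6),
    sigma_Kd_M = c(0.02e-3, 0.06e-3, 0.05e-3, 0.03e-3, 0.02e-3,
                   0.21e-3, 0.7e-3, 44e-9, 28e-9, 0.23e-3,
                   0.03e-6, 0.07e-6),
    kd_digits = c(2, 3, 2, 2, 2, 2, 2, 2, 2, 2, 1, 2),
    dG_kJmol = c(-19.73, -15.99, -17.25, -17.23, -19.10,
                 -19.5, -15.3, -40.1, -40.3, -19.7,
                 -41.3, -40.0),
    sigma_dG_kJmol = c(0.14, 0.09, 0.13, 0.08, 0.11,
                       1.3, 0.8, 1.1, 0.8, 1.6,
                       1.1, 1.6),
    dH_kJmol = c(rep(NA, 10), -25.1, -17.7),
    sigma_dH_kJmol = c(rep(NA, 10), 1.2, 1.7),
    dS_JmolK = c(rep(NA, 10), 47, 70),
    sigma_dS_JmolK = c(rep(NA, 10), 8, 11),
    stringsAsFactors = FALSE
  )
}
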