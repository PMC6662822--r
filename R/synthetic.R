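# Seeded synthetic-data generators.  Each preset reproduces one assay's
# experimental design (18-delay relaxation filter, 4+12x20 ul ITC schedule,
# 7-point dose-response, 300 nM-10 mM titration ranges) with the published
# fitted parameters as generating truth, so every fitting stage can be
# exercised end-to-end without instrument data.

# ---- forward models with noise ---------------------------------------------

#' Simulate an MST or nanoDSF pseudo-titration
#'
#' Two-state signal: linear interpolation between the free and bound
#' signal levels by the exact single-site bound fraction, with additive
#' Gaussian noise scaled to the signal dynamic range and an optional
#' per-replicate baseline offset (run-to-run jitter of the thermophoresis
#' baseline).
#'
#' @param Kd True dissociation constant, M.
#' @param receptor_total Labelled/monitored species concentration, M.
#' @param conc Ligand concentration grid, M.
#' @param S_free,S_bound Signal levels of the free and saturated states.
#' @param replicates Number of replicate series.
#' @param noise_sd Fractional noise (of `|S_bound - S_free|`).
#' @param baseline_jitter_sd Per-replicate baseline shift, same units as the
#'   signal.
#' @param seed Optional integer seed.
#' @return Data frame `conc_M`, `signal`, `replicate`.
#' @export
simulate_titration <- function(Kd, receptor_total, conc,
                               S_free = 800, S_bound = 860,
                               replicates = 3, noise_sd = 0.03,
                               baseline_jitter_sd = 0, seed = NULL) {
  stopifnot_scalar_pos(Kd, "Kd")
  if (noise_sd < 0 || baseline_jitter_sd < 0) stop("noise must be >= 0")
  amp <- S_bound - S_free
  fb <- fraction_bound(receptor_total, conc, Kd)
  with_seed(seed, {
    rows <- lapply(seq_len(replicates), function(r) {
      base <- S_free + stats::rnorm(1, 0, baseline_jitter_sd)
      data.frame(
        conc_M = conc,
        signal = base + amp * fb +
          stats::rnorm(length(conc), 0, noise_sd * abs(amp)),
        replicate = r
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate a nanoDSF melting curve
#'
#' Two-state van't Hoff unfolding monitored as the 350/330 nm fluorescence
#' ratio over a linear thermal ramp. An optional bound peptide depresses the
#' apparent melting temperature in proportion to site occupancy
#' (`Tm = Tm0 - dTm_max * L/(L + Kd_app)`), emulating the
#' concentration-dependent destabilisation seen for these hydrophilic
#' peptide ligands.
#'
#' @param Tm_C Melting temperature of the apo protein, degC.
#' @param dH_vh Van't Hoff unfolding enthalpy, kJ/mol (sets transition width).
#' @param ratio_native,ratio_unfolded 350/330 ratio asymptotes.
#' @param temp_C Temperature grid, degC (default 20-80 at 0.5).
#' @param peptide_conc Peptide concentration, M (0 = apo).
#' @param Kd_app Apparent destabilisation constant, M.
#' @param dTm_max Maximal Tm depression at saturation, degC.
#' @param noise_sd Additive noise on the ratio.
#' @param seed Optional integer seed.
#' @return Data frame `temp_C`, `ratio` with the realised `Tm_C` as an
#'   attribute `"Tm_true"`.
#' @export
simulate_melting_curve <- function(Tm_C = 45, dH_vh = 350,
                                   ratio_native = 0.80,
                                   ratio_unfolded = 0.95,
                                   temp_C = seq(20, 80, by = 0.5),
                                   peptide_conc = 0, Kd_app = 0.35e-3,
                                   dTm_max = 4, noise_sd = 0,
                                   seed = NULL) {
  tm_eff <- Tm_C - dTm_max * peptide_conc / (peptide_conc + Kd_app)
  TK <- temp_C + 273.15
  TmK <- tm_eff + 273.15
  f_unf <- 1 / (1 + exp(dH_vh * 1000 / GAS_CONSTANT * (1 / TK - 1 / TmK)))
  ratio <- ratio_native + (ratio_unfolded - ratio_native) * f_unf
  out <- with_seed(seed, data.frame(
    temp_C = temp_C,
    ratio = ratio + stats::rnorm(length(ratio), 0, noise_sd)
  ))
  attr(out, "Tm_true") <- tm_eff
  out
}

#' Simulate kinase-inhibition dose-response data
#'
#' Luminescent readout proportional to residual kinase activity, falling
#' with inhibitor concentration along a 4PL curve; replicates share the
#' curve and differ only in noise.
#'
#' @param IC50 True IC50, M.
#' @param hill Hill slope.
#' @param top,bottom Response plateaus (uninhibited / fully inhibited).
#' @param conc Concentration grid, M (default 7 log-spaced points,
#'   1 nM-1 mM).
#' @param replicates Number of replicate experiments.
#' @param noise_sd Fractional noise (of `top - bottom`).
#' @param seed Optional integer seed.
#' @return Data frame `conc_M`, `response`, `replicate`.
#' @export
simulate_dose_response <- function(IC50, hill = 1, top = 1e5, bottom = 5e3,
                                   conc = 10^seq(-9, -3, length.out = 7),
                                   replicates = 3, noise_sd = 0.05,
                                   seed = NULL) {
  stopifnot_scalar_pos(IC50, "IC50")
  mu <- .fourpl(conc, IC50, hill, top, bottom)
  with_seed(seed, {
    rows <- lapply(seq_len(replicates), function(r)
      data.frame(conc_M = conc,
                 response = mu + stats::rnorm(length(conc), 0,
                                              noise_sd * abs(top - bottom)),
                 replicate = r))
    do.call(rbind, rows)
  })
}

#' Simulate pull-down LC-MS peak lists
#'
#' Builds unit-resolution peak lists for the three pull-down runs of a
#' positional library: the input library (near-uniform class intensities),
#' the eluent from the protein column (listed classes enhanced by given
#' factors), and the protein-free control column (listed classes enhanced,
#' marking resin binders). Peaks sit at the protonated monoisotopic class
#' masses with a small mass scatter.
#'
#' @param classes An [isobaric_classes()] table.
#' @param enriched Named numeric vector: class key -> eluent intensity
#'   multiplier.
#' @param control_enriched Named numeric vector: class key -> control-run
#'   multiplier (unspecific resin binders).
#' @param base_intensity Mean library-run class intensity.
#' @param intensity_cv Lognormal coefficient of variation of class
#'   intensities.
#' @param mz_sd Gaussian m/z scatter, Da.
#' @param seed Optional integer seed.
#' @return List of data frames `library`, `eluent`, `control`, each with
#'   `mz`, `intensity`, `run`.
#' @export
simulate_pulldown_peaks <- function(classes, enriched = NULL,
                                    control_enriched = NULL,
                                    base_intensity = 1000,
                                    intensity_cv = 0.2, mz_sd = 0.05,
                                    seed = NULL) {
  cterm <- classes$cterm[1] %||% "amide"
  mz_ref <- vapply(classes$members, function(m)
    peptide_mass(m[1], "mono", "protonated", cterm), 0)
  with_seed(seed, {
    base <- base_intensity *
      exp(stats::rnorm(nrow(classes), 0, intensity_cv))
    mk <- function(mult, run) {
      data.frame(mz = mz_ref + stats::rnorm(length(mz_ref), 0, mz_sd),
                 intensity = base * mult, run = run,
                 stringsAsFactors = FALSE)
    }
    mult_of <- function(spec) {
      m <- rep(1, nrow(classes))
      if (!is.null(spec)) {
        idx <- match(names(spec), classes$key)
        if (anyNA(idx)) stop("unknown class key in enrichment spec")
        m[idx] <- spec
      }
      m
    }
    list(library = mk(rep(1, nrow(classes)), "library"),
         eluent = mk(mult_of(enriched), "eluent"),
         control = mk(mult_of(control_enriched), "control"))
  })
}

# ---- scenario presets -------------------------------------------------------

.mst_grid <- function(lo = 1e-7, hi = 1e-2, n = 16) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

.scenarios <- function() {
  rr <- reference_relaxation_rates()
  sc <- list()
  for (i in seq_len(nrow(rr))) {
    sc[[paste0("nmr_", tolower(rr$peptide[i]))]] <- list(
      assay = "nmr", peptide = rr$peptide[i],
      R2f = rr$R2f[i], R2s = rr$R2s[i], n_regions = 6, noise_sd = 0.02,
      description = sprintf("relaxation decay, %s-NH2 rates (%.1f/%.1f 1/s)",
                            rr$peptide[i], rr$R2f[i], rr$R2s[i]))
  }
  mst <- function(kd, who, lo = 1e-7, hi = 1e-2) list(
    assay = "mst", Kd = kd, receptor_total = 5e-8,
    conc = .mst_grid(lo, hi), replicates = 3, noise_sd = 0.03,
    baseline_jitter_sd = 3,
    description = sprintf("MST pseudo-titration, %s (Kd %.3g M)", who, kd))
  sc$mst_keseee <- mst(0.39e-3, "KESEEE-NH2 vs apo")
  sc$mst_rrrdddsddd <- mst(2.1e-3, "RRRDDDSDDD vs apo")
  sc$mst_keseee_tbbt <- mst(0.36e-3, "KESEEE-NH2 vs TBBt complex")
  sc$mst_tbbt <- mst(96e-9, "TBBt vs apo", lo = 1e-9, hi = 1e-4)
  sc$mst_tbbt_keseee <- mst(86e-9, "TBBt vs KESEEE complex",
                            lo = 1e-9, hi = 1e-4)
  sc$dsf_titration <- list(
    assay = "dsf_titration", Kd = 0.35e-3, receptor_total = 2.5e-6,
    conc = 10^seq(log10(3e-7), log10(1e-2), length.out = 16),
    replicates = 1, noise_sd = 0.02, S_free = 0.80, S_bound = 0.74,
    description = "nanoDSF 25 degC ratio slice, KESEEE-NH2 (Kd 0.35 mM)")
  sc$dsf_melt <- list(
    assay = "dsf_melt", Tm_C = 45, peptide_conc = 0, noise_sd = 0.002,
    description = "nanoDSF melting curve, apo protein (Tm 45 degC)")
  sc$dsf_melt_series <- list(
    assay = "dsf_melt_series", Tm_C = 45,
    peptide_conc = c(0, 1e-4, 3e-4, 1e-3, 3e-3, 1e-2), Kd_app = 0.35e-3,
    dTm_max = 4, noise_sd = 0.002,
    description = "melting curves at increasing peptide concentration")
  # 5% heat noise makes the fitted Kd uncertainty match the reported
  # experimental scale (about 50-70% relative), so the cross-dependency
  # verdict is taken at the precision the experiments actually had
  sc$itc_binary <- list(
    assay = "itc", Kd = 0.06e-6, dH = -25.1, n = 1, noise_sd = 0.05,
    n_experiments = 2,
    description = "ITC, protein titrated into TBBt (Kd 0.06 uM)")
  sc$itc_ternary <- list(
    assay = "itc", Kd = 0.10e-6, dH = -17.7, n = 1, noise_sd = 0.05,
    n_experiments = 2,
    description = "ITC with saturating peptide present (Kd 0.10 uM)")
  ic <- function(ic50, who) list(
    assay = "ic50", IC50 = ic50, hill = 1, replicates = 3, noise_sd = 0.05,
    description = sprintf("kinase inhibition dose-response, %s (IC50 %.3g M)",
                          who, ic50))
  sc$ic50_bisubstrate <- ic(0.67e-6, "bi-substrate conjugate")
  sc$ic50_tbbt <- ic(0.62e-6, "TBBt")
  sc$ic50_parent <- ic(8.0e-6, "7-COOH-Br3Bt parent")
  sc$ms_pulldown <- list(
    assay = "ms_pulldown",
    description = "pull-down peak lists; EETEED 6-member class tripled in eluent")
  sc
}

#' List the built-in synthetic scenarios
#'
#' @return Data frame with `scenario` and `description`.
#' @examples
#' head(scenario_presets())
#' @export
scenario_presets <- function() {
  sc <- .scenarios()
  data.frame(scenario = names(sc),
             description = vapply(sc, `[[`, "", "description"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a synthetic assay dataset
#'
#' Dispatches on the scenario's assay type and returns the raw data table
#' the corresponding fitting function consumes, together with the generating
#' truth. Identical scenario and seed give identical output; changing the
#' seed changes only the noise realisation, never the design.
#'
#' @param scenario A preset name from [scenario_presets()].
#' @param seed Integer seed for the noise.
#' @param noise_sd Optional override of the preset noise level (fractional).
#' @return List with elements `scenario`, `data` (assay-appropriate data
#'   frame, or list of experiments for ITC / list of runs for MS), and
#'   `truth` (the generating parameters).
#' @examples
#' d <- generate_scenario("nmr_keseee", seed = 7)
#' head(d$data)
#' @export
generate_scenario <- function(scenario, seed = 1, noise_sd = NULL) {
  sc <- .scenarios()
  if (!scenario %in% names(sc))
    stop("unknown scenario '", scenario, "'; see scenario_presets()")
  p <- sc[[scenario]]
  if (!is.null(noise_sd)) {
    p$noise_sd <- noise_sd
    # noise_sd = 0 means fully noise-free, including replicate jitter
    if (noise_sd == 0 && !is.null(p$baseline_jitter_sd))
      p$baseline_jitter_sd <- 0
  }
  out <- switch(
    p$assay,
    nmr = {
      params <- replicate(p$n_regions, simplify = FALSE,
                          biexp_params(A1 = 1, A2 = 1,
                                       R2f = p$R2f, R2s = p$R2s, y0 = 0))
      # region amplitudes of order 1, deterministic per design
      for (j in seq_along(params)) {
        params[[j]]$A1 <- 0.6 + 0.1 * j
        params[[j]]$A2 <- 1.4 - 0.1 * j
      }
      list(data = simulate_decay(params, nmr_filter_delays(),
                                 regions = paste0("region", seq_len(p$n_regions)),
                                 noise_sd = p$noise_sd, seed = seed),
           truth = list(R2f = p$R2f, R2s = p$R2s, peptide = p$peptide))
    },
    mst = list(
      data = simulate_titration(p$Kd, p$receptor_total, p$conc,
                                replicates = p$replicates,
                                noise_sd = p$noise_sd,
                                baseline_jitter_sd = p$baseline_jitter_sd,
                                seed = seed),
      truth = list(Kd = p$Kd, receptor_total = p$receptor_total)),
    dsf_titration = list(
      data = simulate_titration(p$Kd, p$receptor_total, p$conc,
                                S_free = p$S_free, S_bound = p$S_bound,
                                replicates = p$replicates,
                                noise_sd = p$noise_sd, seed = seed),
      truth = list(Kd = p$Kd, receptor_total = p$receptor_total)),
    dsf_melt = {
      d <- simulate_melting_curve(Tm_C = p$Tm_C,
                                  peptide_conc = p$peptide_conc,
                                  noise_sd = p$noise_sd, seed = seed)
      list(data = d, truth = list(Tm_C = attr(d, "Tm_true")))
    },
    dsf_melt_series = {
      curves <- lapply(seq_along(p$peptide_conc), function(i)
        simulate_melting_curve(Tm_C = p$Tm_C,
                               peptide_conc = p$peptide_conc[i],
                               Kd_app = p$Kd_app, dTm_max = p$dTm_max,
                               noise_sd = p$noise_sd, seed = seed + i - 1))
      d <- do.call(rbind, Map(function(cv, cc)
        cbind(cv, conc_M = cc), curves, p$peptide_conc))
      list(data = d,
           truth = list(Tm_C = vapply(curves, attr, 0, "Tm_true"),
                        conc_M = p$peptide_conc))
    },
    itc = {
      exps <- lapply(seq_len(p$n_experiments), function(i)
        simulate_itc(p$Kd, p$dH, p$n, itc_design(),
                     noise_sd = p$noise_sd, seed = seed + i - 1))
      list(data = exps, truth = list(Kd = p$Kd, dH = p$dH, n = p$n))
    },
    ic50 = list(
      data = simulate_dose_response(p$IC50, hill = p$hill,
                                    replicates = p$replicates,
                                    noise_sd = p$noise_sd, seed = seed),
      truth = list(IC50 = p$IC50, hill = p$hill)),
    ms_pulldown = {
      peps <- enumerate_library(
        library_spec(c("KGDE", "DE", "ST", "DE", "DE", "DE")))
      cls <- isobaric_classes(peps)
      key750 <- cls$key[vapply(cls$members, function(m) "EETEED" %in% m, TRUE)]
      key763 <- cls$key[vapply(cls$members, function(m) "KETEEE" %in% m, TRUE)]
      key764 <- cls$key[vapply(cls$members, function(m) "EETEEE" %in% m, TRUE)]
      keyctrl <- cls$key[vapply(cls$members, function(m) "GDTDDD" %in% m, TRUE)]
      enr <- stats::setNames(c(3, 2.5, 2.2), c(key750, key763, key764))
      ctl <- stats::setNames(3, keyctrl)
      runs <- simulate_pulldown_peaks(cls, enriched = enr,
                                      control_enriched = ctl, seed = seed)
      list(data = runs,
           truth = list(classes = cls, enriched = enr,
                        control_enriched = ctl, top_class_key = key750))
    },
    stop("unknown assay type")
  )
  c(list(scenario = scenario), out)
}
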