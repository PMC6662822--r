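---
title: "Screening a peptide leader for a bi-substrate kinase inhibitor: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a peptide leader for a bi-substrate kinase inhibitor: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptherm)
```

`peptherm` implements the computational workflow behind selecting the
peptide half of a bi-substrate inhibitor of protein kinase CK2: a
consensus-derived combinatorial library is screened by pull-down
mass spectrometry, candidates are ranked by a relaxation-filtered NMR
observable, affinities are quantified by nanoDSF, MST and ITC, the
independence of peptide and ATP-site ligand binding is tested, and the
potency gain of the final conjugate is measured. This vignette documents
the models, the tunable parameters, the synthetic-data generators that
stand in for the instruments, and the numerical and design decisions —
including the ones where reasonable alternatives existed.

## Library enumeration and mass deconvolution

A positional library `[KGDE]-[DE]-[ST]-[DE]-[DE]-[DE]` with an amide
C-terminus enumerates to the Cartesian product of its position sets,
4×2×2×2×2×2 = 128 hexapeptides. Masses are residue-additive: the neutral
peptide is the sum of residue masses plus one water (free acid) or one
ammonia (C-terminal amide, 17.026549 Da monoisotopic); protonation adds
1.007276 Da (monoisotopic) or 1.008 Da (average).

```{r masses}
peptide_mass(c("KETEEE", "EETEED", "EETEEE"), adduct = "protonated")
```

Unit-resolution ESI-MS peak labels such as "750 Da" are interpreted as the
nominal (integer-rounded) protonated monoisotopic mass: this convention
reproduces all three printed peak identities above (763, 750, 764).
Average masses are also computed and reported, since the raw spectra do
not state their convention; the choice is a documented setting of
`assign_peaks()` (`kind = "mono"` by default).

Acidic libraries are systematically mass-degenerate because the residue
pairs Thr+Asp and Glu+Ser share the elemental composition C₈H₁₂N₂O₅.
Grouping therefore uses the exact elemental formula as the class key
(`isobaric_classes()`, `policy = "composition"`); a mass-tolerance policy
(single-linkage clustering with tolerance ε) is provided for lower-purity
data, and every composition class is contained in a tolerance class for
any ε > 0. The class containing EETEED-NH₂ has exactly six members — five
permutations of {E₄, T, D} reachable within the library grammar plus
EESEEE-NH₂ via the composition identity.

Enrichment scoring normalises each run (library, eluent, protein-free
control) by total ion intensity, sums intensities per class, and ranks
classes by the eluent/library ratio. Classes whose control/library ratio
exceeds 1.5 are flagged unspecific (resin binders) and excluded. The
normalisation mode and threshold are arguments; the defaults are a
judgement call since the source spectra carry no absolute scale — total-ion
normalisation is the least-assuming choice for run-to-run comparison, and
1.5 separates clearly control-enhanced classes from ratio noise at the
generator's 20% intensity dispersion.

## Relaxation-filtered NMR ranking

With a transverse-relaxation filter of delay $t$ the ligand signal decays
as

$$y(t) = A_1 e^{-R_{2,f} t} + A_2 e^{-R_{2,s} t} + y_0,$$

where $R_{2,f}$ is the exchange-averaged rate of the protein-sensing
fraction and $R_{2,s}$ that of free peptide. Note the decaying sign
convention: intensities fall with increasing delay, so the exponents are
negative. The experiment uses 18 delays from 0 to 200 ms
(`nmr_filter_delays()`), and six resonance regions per peptide are fitted
*globally*: rates shared, per-region amplitudes free (regions differ in
proton count and hence intensity, but the rates are molecular properties).

Two numerical choices matter here.

- **Baseline offset.** By default `fit_biexp_global()` fixes $y_0 = 0$
  (`offset = "zero"`): a relaxation filter drives the baseline-corrected
  intensity to zero, and over a 0–200 ms window a slow rate of a few s⁻¹
  produces so little curvature ($R_{2,s} t_{\max} \le 0.5$) that a free
  per-region offset is nearly collinear with the slow exponential. With
  free offsets the five-parameter-per-region model is practically
  unidentifiable at realistic noise — in our simulations the fitted fast
  rate for a true 7.1 s⁻¹ could land anywhere up to ~90 s⁻¹ — while with
  $y_0 = 0$ the same data return 5–10 s⁻¹ across seeds. `offset = "free"`
  remains available for data with genuine baseline offsets.
- **Initialisation and canonical order.** The slow rate is started from a
  log-linear fit of the late-delay tail, with additional spread starts
  (10, 30, 80 s⁻¹) for the fast rate; rates are bounded to [0, 500] s⁻¹.
  Because the two components are exchangeable, the fit is canonicalised to
  $R_{2,f} \ge R_{2,s}$ after convergence. Uncertainties come from the
  least-squares covariance; 95% intervals use the t quantile at the
  residual degrees of freedom.

`rank_peptides()` orders by $R_{2,f}$, breaking ties with
$R_{2,f}/R_{2,s}$. Converting $R_{2,f}$ to an absolute bound population
would require the protein's own relaxation rate, which is not available —
the module deliberately ranks rather than quantifies.

## Single-site binding and thermodynamics

All titrations use the exact 1:1 mass balance — `fraction_bound()` solves
the quadratic in its numerically stable form (no free-ligand
approximation, important at receptor concentrations near $K_d$). Isotherm
fits (`fit_isotherm()`) model the signal as a linear interpolation between
free and bound levels; for MST this two-state thermophoresis model is the
minimal standard choice, the instrument vendor's exact signal equation
being unpublished. $K_d$ is fitted on the log scale (bounds $10^{-12}$–1 M,
five log-spaced starts), replicates share $K_d$ and amplitude with a free
per-replicate baseline, and a `conc_max` cutoff can exclude
high-concentration points where ~1 mM peptide unfolds the protein and
distorts the MST trace; the cutoff used is recorded on the fit object.

Free energies use $\Delta G = RT\,\ln(K_d/1\,\mathrm{M})$ with
$R = 8.314$ J mol⁻¹ K⁻¹, $T = 298.15$ K for 25 °C (348.15 K for 75 °C),
with errors propagated as $\sigma_{\Delta G} = RT\,\sigma_{K_d}/K_d$ and
$\sigma_{\Delta S} = \sqrt{\sigma_{\Delta G}^2 + \sigma_{\Delta H}^2}/T$.
These conventions reproduce every printed $K_d$/$\Delta G$ pair in the
reference table (`reference_thermo_table()`) to 0.06 kJ/mol — except that
a $K_d$ printed with one significant figure (0.06 µM) carries a
rounding-induced $\Delta G$ half-width of ~0.2 kJ/mol, which the
self-consistency tests account for explicitly rather than pretending the
printed digit is exact.

Melting temperatures are extracted from the 350/330 nm ratio curve as the
extremum of the first derivative of a cross-validated smoothing spline;
flat curves or boundary extrema raise a `peptherm_no_transition` error
rather than returning a spurious $T_m$.

## ITC

The titration is a *reverse* design: ATP-site ligand in the 950 µl cell,
protein in the syringe, one 4 µl pre-injection followed by twelve 20 µl
injections. The displacement convention is the standard perfusion-cell
correction: each injection expels its volume of *pre-injection* cell
content, then the injected titrant mixes in; per-injection heat is
$\Delta H$ times the change of complex in the active volume (including
complex lost to the overflow). The simulator and fitter share this
bookkeeping, but the equilibrium itself is cross-checked in the tests
against an independent bisection solver. The apparent stoichiometry $n$
multiplies the cell-species concentration, mirroring the one-site model
of the instrument software; because the model treats the binding pair
symmetrically, putting the ligand rather than the protein in the cell
leaves $K_d$ unaffected. A Wiseman $c$-value (cell concentration / $K_d$)
outside [1, 1000] triggers a warning that the curve shape poorly
determines $K_d$ (the preset design has $c \approx 83$).

## Dose–response

`fit_ic50()` fits the four-parameter logistic globally across replicates
in log-concentration, $IC_{50}$ on the log scale, Hill slope bounded to
[0.3, 4] (free by default; plateaus can be fixed, since whether the
original analysis fixed them is unstated). Data whose response range is
below three times the replicate noise raise an unidentifiability error
instead of returning an arbitrary $IC_{50}$. `fold_enhancement()` is the
parent/derived ratio with quotient error propagation.

## Cross-dependency (ternary) test

Whether peptide and ATP-site ligand bind independently is decided on the
log-$K_d$ scale, where experimental errors are approximately
multiplicative:

$$z = \frac{|\ln K_d^{apo} - \ln K_d^{complex}|}
          {\sqrt{(\sigma_a/K_a)^2 + (\sigma_c/K_c)^2}},$$

with verdict "independent" when $z < z_{1-\alpha/2}$ (α = 0.05 by
default) and the coupling free energy
$RT\,\ln(K_d^{complex}/K_d^{apo})$ reported alongside. The original
qualitative judgement ("the same within experimental error") is thereby
made explicit and configurable.

## Synthetic data: what it emulates and what it does not

Every preset in `scenario_presets()` reproduces one assay's published
design and uses the published fitted parameters as generating truth:
18-delay decays at the tabulated rate pairs for ten peptides; 16-point,
three-replicate MST titrations (100 nM–10 mM, 50 nM labelled receptor)
with per-replicate baseline jitter; 20–80 °C melting curves with
occupancy-proportional $T_m$ depression; the 4+12×20 µl ITC schedule at
5 µM cell ligand and 40 µM syringe protein (the methods give 4–10 µM and
20–60 µM ranges; the defaults are mid-range and configurable); and
7-point, three-replicate dose–response curves spanning 1 nM–1 mM.

Noise levels are not printed anywhere, so they were chosen once on two
principles and not revisited: recovery-style assays (NMR 2%, MST 3%,
dose–response 5% of dynamic range) use values typical of the respective
instruments, and the ITC presets use 5% of the maximal heat — the level at
which the fitted $\sigma_{K_d}/K_d$ (~45%) matches the *reported*
experimental uncertainties (50–70%). The last point matters
scientifically: the binary and ternary generating truths (0.06 µM vs
0.10 µM) genuinely differ, and a sufficiently precise synthetic experiment
resolves them. The published independence claim holds *at the experiments'
actual precision*, and the pipeline's verdict is only meaningful when the
synthetic uncertainty matches it. At 2% heat noise roughly half of the
seeds would (correctly, for the synthetic truth) call the difference
significant.

What the generators do **not** emulate: raw spectra or thermograms
(intensities are already integrated), charge states beyond \[M+H\]⁺,
LC retention behaviour, baseline drift within a run, protein aggregation,
or the concentration errors that dominate real ITC accuracy. Passing
recovery tests therefore demonstrates the estimators are correct and
calibrated for the stated error model, not that the pipeline is robust to
every instrumental artefact.

## Problem sizes

The test-suite and acceptance runs use the sizes a desk check needs, as
this package's own choice: 20 noise realisations per recovery target
(coverage asserted at ≥ 90% of nominal 95%), 10–15 seeds per cell of the
bias grids, and two joint ITC experiments per fit, matching the "at least
two titrations" of the source protocol. The full pipeline takes on the
order of a second.

## Known limitations

- The relaxation module ranks; it does not estimate bound fractions or
  exchange rates.
- The ternary ITC fit is an *apparent* one-site model in the presence of
  saturating peptide, not a three-species equilibrium; the explicit
  thermodynamic cycle is out of scope.
- No Cheng–Prusoff conversion of $IC_{50}$ to $K_i$ (the assay's ATP/Km
  context is not modelled).
- Readers for instrument-native file formats are deliberately absent; the
  package consumes plain CSV tables.
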