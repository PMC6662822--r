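# peptherm

Thermodynamic screening of peptide leaders for bi-substrate kinase
inhibitors.

Bi-substrate kinase inhibitors couple an ATP-competitive ligand to a
peptide that occupies the substrate-recognition site, gaining specificity
that ATP-site binders alone cannot deliver. Choosing the peptide part is a
screening problem: enumerate a consensus-derived combinatorial library,
identify which members a pull-down enriches, rank candidates by a
binding-sensitive NMR observable, quantify affinities by orthogonal
biophysical assays, and — critically — verify that peptide and ATP-site
ligand bind *independently*, so that fusing them is thermodynamically
additive. `peptherm` implements that whole computational workflow for the
catalytic subunit of human protein kinase CK2 (hCK2α) as the model target,
with seeded synthetic-data generators emulating every assay so the
pipeline runs end-to-end without instrument data.

## The models

- **Library deconvolution.** A positional library such as
  `[KGDE]-[DE]-[ST]-[DE]₃-NH₂` is the Cartesian product of its position
  sets (here 4·2·2·2³ = 128 hexapeptides). Unit-resolution ESI-MS cannot
  distinguish peptides with the same elemental composition; in acidic
  libraries the residue-pair identity Thr+Asp = Glu+Ser (both C₈H₁₂N₂O₅)
  makes such degeneracy systematic, so peaks are assigned to *isobaric
  classes* (exact-composition partition) rather than single sequences, and
  pull-down enrichment is scored per class as the normalised
  eluent/library intensity ratio, excluding classes the protein-free
  control column also retains.
- **Relaxation ranking.** With a relaxation filter of delay *t*, ligand
  signal decays bi-exponentially,
  `y(t) = A₁·exp(−R₂,f·t) + A₂·exp(−R₂,s·t) + y₀`: the fast rate `R₂,f`
  reports the exchange-averaged, protein-bound fraction, the slow rate
  `R₂,s` the free peptide. Decays from all resonance regions are fitted
  globally (shared rates, free per-region amplitudes) and peptides ranked
  by `R₂,f`.
- **Single-site binding.** The bound fraction is the exact root of the
  1:1 mass balance, `[RL]² − (R₀+L₀+K_d)[RL] + R₀L₀ = 0`; nanoDSF ratio
  slices and MST pseudo-titrations are fitted as
  `S = S_free + (S_bound − S_free)·f_b`, ITC heats by the one-site
  perfusion-cell model, and IC₅₀ curves by the four-parameter logistic.
  `ΔG = RT·ln(K_d/1 M)`, `ΔS = (ΔH − ΔG)/T`, with first-order error
  propagation throughout.
- **Cross-dependency.** Independence of the two sites is tested on the
  log-K_d scale: `z = |ln K_d^apo − ln K_d^complex| / √((σ_a/K_a)² +
  (σ_c/K_c)²)`, with verdict "independent" when `z` is below the two-sided
  normal quantile.

## Worked example

```r
library(peptherm)

# which peptides can a 750 Da peak even mean?
peps <- enumerate_library(library_spec(c("KGDE","DE","ST","DE","DE","DE")))
cls  <- isobaric_classes(peps)
assign_peaks(data.frame(mz = 750.28, intensity = 100), cls)[1, c("n_members","mass_error")]
#>   n_members mass_error
#> 1         6 0.001181016

# the full synthetic screening pipeline
run_pipeline(seed = 1)
#> Peptide-leader screening pipeline (seed 1 )
#>   [ok] enrichment
#>   [ok] relaxation_ranking
#>   [ok] binding_affinity
#>   [ok] ternary
#>   [ok] potency
#>   top-ranked peptide: KESEEE
#>   lead Kd = 0.000411 M (dG = -19.32 kJ/mol); reference Kd = 0.00215 M
#>   cross-dependency: peptide independent, ATP-site ligand independent
#>   IC50 bisubstrate = 8.31e-07 M; fold enhancement over parent = 11.0
```

Reading the report: the six-member 750 Da isobaric class tops the
enrichment table; KESEEE-NH₂ ranks first by `R₂,f` and its fitted MST
K_d (~0.4 mM, ΔG ≈ −19.3 kJ/mol) is about five-fold stronger than the
reference substrate decapeptide; neither ligand's K_d shifts significantly
when the other site is occupied ("independent"), so the conjugate is
expected to work — and its fitted IC₅₀ (~0.7 µM) improves on the parent
acid by more than ten-fold.

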