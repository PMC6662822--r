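# Independent numerical oracles used to cross-check closed-form solutions.

# Bound fraction by bisection on the 1:1 mass balance
# (R_free * L_free = Kd * RL, with R_free = R0 - RL, L_free = L0 - RL),
# independent of the quadratic formula used in the package.
bisect_fraction_bound <- function(R0, L0, Kd, tol = 1e-16) {
  if (R0 == 0 || L0 == 0) return(0)
  f <- function(rl) (R0 - rl) * (L0 - rl) - Kd * rl
  lo <- 0; hi <- min(R0, L0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(hi, 1e-300)) break
  }
  (lo + hi) / 2 / R0
}

# Per-injection ITC heats from a bisection equilibrium solver under the same
# displacement convention (overflow leaves at pre-injection concentrations),
# independent of the package's closed-form complex concentration.
oracle_itc_heats <- function(Kd, dH, n, design, Q0 = 0) {
  V0 <- design$cell_volume_ul * 1e-6
  X <- design$cell_conc; M <- 0; C_prev <- 0
  heats <- numeric(length(design$injection_volumes_ul))
  for (i in seq_along(heats)) {
    v <- design$injection_volumes_ul[i] * 1e-6
    f <- 1 - v / V0
    X <- X * f
    M <- M * f + design$syringe_conc * v / V0
    S <- n * X
    C_new <- S * bisect_fraction_bound(S, M, Kd)
    heats[i] <- dH * (C_new - C_prev * f) * V0 * 1e9 + Q0
    C_prev <- C_new
  }
  heats
}

# Random positional library specs for enumeration-count property tests.
random_library_spec <- function() {
  aas <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
           "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")
  npos <- sample(2:5, 1)
  positions <- vapply(seq_len(npos), function(i)
    paste(sample(aas, sample(1:4, 1)), collapse = ""), "")
  library_spec(positions, cterm = sample(c("amide", "free-acid"), 1))
}
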