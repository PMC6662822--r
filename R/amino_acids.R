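# Residue-level mass and elemental-composition tables for the 20 standard
# amino acids.  Masses are residue masses (monomer minus water); a peptide is
# the residue sum plus one water (free acid) or one ammonia (C-terminal amide).

# Elemental composition of each residue: C, H, N, O, S counts.
.AA_ELEMENTS <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 0, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

# Monoisotopic atomic masses (Da).
.ATOM_MONO <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
# Average atomic masses (Da).
.ATOM_AVG <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994, S = 32.065)

.AA_MONO <- drop(.AA_ELEMENTS %*% .ATOM_MONO)
.AA_AVG  <- drop(.AA_ELEMENTS %*% .ATOM_AVG)

# Terminal adjustments: free acid adds H2O, amide terminus adds NH3.
.WATER_MONO   <- 2 * .ATOM_MONO[["H"]] + .ATOM_MONO[["O"]]    # 18.010565
.WATER_AVG    <- 2 * .ATOM_AVG[["H"]] + .ATOM_AVG[["O"]]
.AMMONIA_MONO <- 3 * .ATOM_MONO[["H"]] + .ATOM_MONO[["N"]]    # 17.026549
.AMMONIA_AVG  <- 3 * .ATOM_AVG[["H"]] + .ATOM_AVG[["N"]]
.PROTON_MONO  <- 1.007276
.PROTON_AVG   <- 1.008

.check_residues <- function(residues) {
  bad <- setdiff(residues, rownames(.AA_ELEMENTS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  invisible(residues)
}

#' Elemental formula of a peptide
#'
#' Sums residue compositions and adds the terminal group (water for a free
#' acid, ammonia for a C-terminal amide), returning a canonical formula
#' string such as `"C30H47N7O16"` that serves as the exact-composition key
#' for isobaric grouping.
#'
#' @param sequence One-letter residue string, e.g. `"KESEEE"`.
#' @param cterm C-terminal state, `"amide"` or `"free-acid"`.
#' @return A single formula string in CHNOS order, zero-count elements omitted.
#' @examples
#' peptide_formula("EESEEE", cterm = "amide")
#' @export
peptide_formula <- function(sequence, cterm = c("amide", "free-acid")) {
  cterm <- match.arg(cterm)
  residues <- strsplit(sequence, "")[[1]]
  .check_residues(residues)
  counts <- colSums(.AA_ELEMENTS[residues, , drop = FALSE])
  if (cterm == "free-acid") {
    counts["H"] <- counts["H"] + 2; counts["O"] <- counts["O"] + 1
  } else {
    counts["H"] <- counts["H"] + 3; counts["N"] <- counts["N"] + 1
  }
  paste0(names(counts)[counts > 0], counts[counts > 0], collapse = "")
}

#' Peptide mass
#'
#' Neutral or protonated mass of a peptide from residue masses plus the
#' terminal group. The protonated monoisotopic mass rounded to the nearest
#' integer is the nominal mass convention used when matching unit-resolution
#' ESI-MS peaks.
#'
#' @param sequence One-letter residue string (vectorised).
#' @param kind `"mono"` (monoisotopic) or `"avg"` (average).
#' @param adduct `"neutral"` or `"protonated"` (adds 1.007276 Da mono /
#'   1.008 Da average).
#' @param cterm C-terminal state, `"amide"` or `"free-acid"`.
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("KETEEE", adduct = "protonated")       # ~763.35
#' round(peptide_mass("EETEED", adduct = "protonated")) # 750
#' @export
peptide_mass <- function(sequence, kind = c("mono", "avg"),
                         adduct = c("neutral", "protonated"),
                         cterm = c("amide", "free-acid")) {
  kind <- match.arg(kind); adduct <- match.arg(adduct); cterm <- match.arg(cterm)
  res_mass <- if (kind == "mono") .AA_MONO else .AA_AVG
  term <- if (kind == "mono") {
    if (cterm == "free-acid") .WATER_MONO else .AMMONIA_MONO
  } else {
    if (cterm == "free-acid") .WATER_AVG else .AMMONIA_AVG
  }
  proton <- if (adduct == "protonated") {
    if (kind == "mono") .PROTON_MONO else .PROTON_AVG
  } else 0
  vapply(sequence, function(s) {
    residues <- strsplit(s, "")[[1]]
    .check_residues(residues)
    sum(res_mass[residues]) + term + proton
  }, numeric(1), USE.NAMES = FALSE)
}
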