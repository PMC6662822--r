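# Positional combinatorial peptide libraries: enumeration, isobaric
# grouping, MS peak assignment and pull-down enrichment scoring.

#' Define a positional peptide library
#'
#' A library is an ordered list of residue alternatives per position, e.g.
#' `[KGDE]-[DE]-[ST]-[DE]-[DE]-[DE]` with an amidated C-terminus — the
#' consensus-derived hexapeptide library screened against the CK2 catalytic
#' subunit. The enumerated library is the Cartesian product of the position
#' sets.
#'
#' @param positions Character vector, one string of one-letter residue codes
#'   per position (e.g. `c("KGDE", "DE", "ST", "DE", "DE", "DE")`).
#' @param cterm C-terminal state, `"amide"` or `"free-acid"`.
#' @param name Optional text label.
#' @return An object of class `"library_spec"`.
#' @examples
#' spec <- library_spec(c("KGDE", "DE", "ST", "DE", "DE", "DE"))
#' library_size(spec)  # 128
#' @export
library_spec <- function(positions, cterm = c("amide", "free-acid"),
                         name = NULL) {
  cterm <- match.arg(cterm)
  if (!is.character(positions) || length(positions) == 0)
    stop("'positions' must be a non-empty character vector")
  sets <- lapply(positions, function(p) unique(strsplit(p, "")[[1]]))
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("every position must offer at least one residue")
  lapply(sets, .check_residues)
  structure(list(positions = sets, cterm = cterm,
                 name = name %||% paste0("[", positions, "]", collapse = "-")),
            class = "library_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname library_spec
#' @param spec A `library_spec`.
#' @export
library_size <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  prod(vapply(spec$positions, length, integer(1)))
}

#' @export
print.library_spec <- function(x, ...) {
  cat("Peptide library", x$name, sprintf("(%s C-terminus)\n", x$cterm))
  cat("  positions:", paste(vapply(x$positions, paste, "", collapse = ""),
                            collapse = " | "), "\n")
  cat("  size:", library_size(x), "peptides\n")
  invisible(x)
}

#' Enumerate a peptide library
#'
#' Expands the full Cartesian product of the position sets into a peptide
#' table with neutral monoisotopic and average masses and the elemental
#' formula of each member. The row count equals the product of the position
#' set sizes.
#'
#' @param spec A [library_spec()].
#' @return A `data.frame` of class `"peptide_library"` with columns
#'   `sequence`, `cterm`, `formula`, `mono_mass`, `avg_mass`.
#' @examples
#' peps <- enumerate_library(library_spec(c("KGDE", "DE", "ST", "DE", "DE", "DE")))
#' nrow(peps)  # 128
#' @export
enumerate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  grid <- expand.grid(rev(spec$positions), stringsAsFactors = FALSE)
  seqs <- do.call(paste0, rev(grid))
  out <- data.frame(
    sequence = seqs,
    cterm = spec$cterm,
    formula = vapply(seqs, peptide_formula, "", cterm = spec$cterm,
                     USE.NAMES = FALSE),
    mono_mass = peptide_mass(seqs, "mono", "neutral", spec$cterm),
    avg_mass = peptide_mass(seqs, "avg", "neutral", spec$cterm),
    stringsAsFactors = FALSE
  )
  class(out) <- c("peptide_library", "data.frame")
  out
}

#' Group peptides into isobaric classes
#'
#' Peptides indistinguishable by mass are grouped into classes; peak
#' assignment then maps an MS peak to a whole class rather than a single
#' sequence. Under the `"composition"` policy the key is the exact elemental
#' formula, so peptides related by the threonine+aspartate =
#' glutamate+serine composition identity (both residue pairs are C8H12N2O5)
#' fall in one class. Under `"mass"` peptides are clustered by monoisotopic
#' mass with tolerance `tol` (single-linkage on the sorted masses, so any
#' two members of a chain closer than `tol` share a class).
#'
#' @param peptides A `peptide_library` data frame (or any data frame with
#'   `sequence`, `formula`, `mono_mass` columns).
#' @param policy `"composition"` (exact elemental formula) or `"mass"`.
#' @param tol Mass tolerance in Da for the `"mass"` policy; must be >= 0.
#' @return A data frame of class `"isobaric_classes"` with one row per class:
#'   `class`, `key`, `mono_mass` (class mean), `n_members`, and a list column
#'   `members` of sequence vectors.
#' @examples
#' peps <- enumerate_library(library_spec(c("KGDE", "DE", "ST", "DE", "DE", "DE")))
#' cls <- isobaric_classes(peps)
#' cls$members[[which(vapply(cls$members, function(m) "EETEED" %in% m, TRUE))]]
#' @export
isobaric_classes <- function(peptides, policy = c("composition", "mass"),
                             tol = 0.01) {
  policy <- match.arg(policy)
  if (nrow(peptides) == 0) stop("'peptides' must be non-empty")
  if (policy == "mass") {
    if (!is.numeric(tol) || tol < 0) stop("'tol' must be >= 0")
    ord <- order(peptides$mono_mass)
    m <- peptides$mono_mass[ord]
    grp <- cumsum(c(1, diff(m) > tol))
    key <- vapply(split(m, grp), function(v) sprintf("%.4f", mean(v)), "")
    idx <- split(ord, grp)
  } else {
    key <- unique(peptides$formula)
    idx <- split(seq_len(nrow(peptides)),
                 factor(peptides$formula, levels = key))
  }
  out <- data.frame(
    class = seq_along(idx),
    key = unname(key),
    mono_mass = vapply(idx, function(i) mean(peptides$mono_mass[i]), 0),
    n_members = vapply(idx, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$members <- unname(lapply(idx, function(i) sort(peptides$sequence[i])))
  out$cterm <- peptides$cterm[1]
  class(out) <- c("isobaric_classes", "data.frame")
  out
}

#' Assign MS peaks to isobaric classes
#'
#' Matches each observed m/z against the protonated monoisotopic mass
#' (singly charged \[M+H\]+ by default) of every class; a peak can match
#' several classes if masses are close, and peaks matching no class are
#' reported with `class = NA` rather than dropped.
#'
#' @param peaks Data frame with columns `mz`, `intensity` and optionally
#'   `run`.
#' @param classes An [isobaric_classes()] table.
#' @param tolerance Match tolerance in Da (> 0). Default 0.5 Da suits
#'   unit-resolution ESI-MS.
#' @param kind Mass convention for the class reference mass, `"mono"` or
#'   `"avg"`.
#' @return Data frame with one row per (peak, matched class) pair:
#'   `mz`, `intensity`, `run`, `class`, `key`, `n_members`, `mass_error`
#'   (observed minus reference, Da), `assigned`.
#' @examples
#' peps <- enumerate_library(library_spec(c("KGDE", "DE", "ST", "DE", "DE", "DE")))
#' cls <- isobaric_classes(peps)
#' assign_peaks(data.frame(mz = 750.28, intensity = 100), cls)
#' @export
assign_peaks <- function(peaks, classes, tolerance = 0.5,
                         kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  stopifnot_scalar_pos(tolerance, "tolerance")
  if (!all(c("mz", "intensity") %in% names(peaks)))
    stop("'peaks' needs columns mz and intensity")
  if (any(peaks$mz <= 0) || any(peaks$intensity < 0))
    stop("peaks must have mz > 0 and intensity >= 0")
  run <- if ("run" %in% names(peaks)) peaks$run else NA_character_
  cterm <- classes$cterm[1] %||% "amide"
  ref <- vapply(classes$members, function(m)
    peptide_mass(m[1], kind, "protonated", cterm), 0)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    hit <- which(abs(peaks$mz[i] - ref) <= tolerance)
    if (length(hit) == 0)
      return(data.frame(mz = peaks$mz[i], intensity = peaks$intensity[i],
                        run = run[min(i, length(run))], class = NA_integer_,
                        key = NA_character_, n_members = NA_integer_,
                        mass_error = NA_real_, assigned = FALSE,
                        stringsAsFactors = FALSE))
    data.frame(mz = peaks$mz[i], intensity = peaks$intensity[i],
               run = run[min(i, length(run))], class = classes$class[hit],
               key = classes$key[hit], n_members = classes$n_members[hit],
               mass_error = peaks$mz[i] - ref[hit], assigned = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score pull-down enrichment per isobaric class
#'
#' Compares three LC-MS runs of the same library: the input library, the
#' eluent recovered after passing the library over the immobilised-protein
#' column, and a control run over resin without protein. Intensities are
#' normalised within each run (total-intensity by default), summed per
#' isobaric class, and each class is scored by its eluent/library ratio;
#' classes whose control/library ratio exceeds `control_threshold` bind the
#' resin itself and are flagged unspecific and excluded from the ranking.
#'
#' @param peaks_library,peaks_eluent,peaks_control Data frames with `mz`,
#'   `intensity`.
#' @param classes An [isobaric_classes()] table.
#' @param tolerance Peak-match tolerance in Da.
#' @param control_threshold Control/library normalised-intensity ratio above
#'   which a class is excluded as unspecific.
#' @param normalization `"total"` (total-ion) or `"max"` (base peak).
#' @return Data frame sorted by decreasing enrichment among retained
#'   classes: `class`, `key`, `n_members`, `members`, `library`, `eluent`,
#'   `control` (normalised intensities), `enrichment`, `control_ratio`,
#'   `unspecific`, `defined`.
#' @export
enrichment_score <- function(peaks_library, peaks_eluent, peaks_control,
                             classes, tolerance = 0.5,
                             control_threshold = 1.5,
                             normalization = c("total", "max")) {
  normalization <- match.arg(normalization)
  norm_class_intensity <- function(peaks) {
    tot <- switch(normalization, total = sum(peaks$intensity),
                  max = max(peaks$intensity))
    if (!is.finite(tot) || tot <= 0) stop("run has no intensity to normalise")
    asg <- assign_peaks(peaks, classes, tolerance)
    asg <- asg[asg$assigned, , drop = FALSE]
    v <- vapply(classes$class, function(cl)
      sum(asg$intensity[asg$class == cl]) / tot, 0)
    v
  }
  lib <- norm_class_intensity(peaks_library)
  elu <- norm_class_intensity(peaks_eluent)
  ctl <- norm_class_intensity(peaks_control)
  defined <- lib > 0
  enr <- ifelse(defined, elu / lib, NA_real_)
  ctl_ratio <- ifelse(defined, ctl / lib, NA_real_)
  unspecific <- defined & ctl_ratio > control_threshold
  out <- data.frame(class = classes$class, key = classes$key,
                    n_members = classes$n_members,
                    library = lib, eluent = elu, control = ctl,
                    enrichment = enr, control_ratio = ctl_ratio,
                    unspecific = unspecific, defined = defined,
                    stringsAsFactors = FALSE)
  out$members <- classes$members
  keep <- out$defined & !out$unspecific
  rbind(out[keep, ][order(-out$enrichment[keep]), ], out[!keep, ])
}
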