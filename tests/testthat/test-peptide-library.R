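# Library enumeration, masses, isobaric grouping, peak assignment and
# pull-down enrichment.

hexa_spec <- library_spec(c("KGDE", "DE", "ST", "DE", "DE", "DE"))
hexa <- enumerate_library(hexa_spec)
hexa_classes <- isobaric_classes(hexa)

test_that("enumeration covers the full Cartesian product", {
  expect_equal(nrow(hexa), 128)
  # heptapeptide screen: two sub-libraries split by the phosphoacceptor
  hepta_s <- enumerate_library(library_spec(c("KGDE", "DE", "S", "DE", "DE", "DE", "DE")))
  hepta_t <- enumerate_library(library_spec(c("KGDE", "DE", "T", "DE", "DE", "DE", "DE")))
  expect_equal(nrow(hepta_s), 128)
  expect_equal(nrow(hepta_t), 128)
  expect_equal(nrow(hepta_s) + nrow(hepta_t), 256)
  # single-choice product
  aa <- enumerate_library(library_spec(c("A", "A"), cterm = "free-acid"))
  expect_equal(aa$sequence, "AA")
  expect_error(library_spec(character(0)))
  expect_error(library_spec(c("KGDE", "")))
})

test_that("enumeration count equals the product of position-set sizes", {
  set.seed(11)
  for (i in 1:100) {
    spec <- random_library_spec()
    expect_equal(nrow(enumerate_library(spec)), library_size(spec))
  }
})

test_that("peptide masses follow the residue-additive conventions", {
  # glycine free acid: C2H5NO2 summed from atomic masses
  expect_equal(peptide_mass("G", "mono", "neutral", "free-acid"),
               75.03203, tolerance = 1e-7)
  # nominal protonated monoisotopic masses of the identified pull-down hits
  expect_equal(round(peptide_mass("EETEED", adduct = "protonated")), 750)
  expect_equal(round(peptide_mass("KETEEE", adduct = "protonated")), 763)
  expect_equal(round(peptide_mass("EETEEE", adduct = "protonated")), 764)
  # protonation adds one proton mass
  expect_equal(peptide_mass("KESEEE", adduct = "protonated") -
                 peptide_mass("KESEEE", adduct = "neutral"),
               1.007276, tolerance = 1e-9)
  expect_true(all(hexa$mono_mass < hexa$avg_mass))
  expect_error(peptide_mass("KEZ"), "unknown residue")
})

test_that("free-acid mass is additive up to one water per bond", {
  water <- 18.010565
  set.seed(7)
  for (i in 1:20) {
    p <- paste(sample(rownames(peptherm:::.AA_ELEMENTS), 4, TRUE), collapse = "")
    q <- paste(sample(rownames(peptherm:::.AA_ELEMENTS), 3, TRUE), collapse = "")
    expect_equal(
      peptide_mass(paste0(p, q), cterm = "free-acid"),
      peptide_mass(p, cterm = "free-acid") + peptide_mass(q, cterm = "free-acid") - water,
      tolerance = 1e-9)
  }
})

test_that("the class containing EETEED has exactly the six expected members", {
  i <- which(vapply(hexa_classes$members, function(m) "EETEED" %in% m, TRUE))
  expect_equal(sort(hexa_classes$members[[i]]),
               sort(c("EETEED", "EETEDE", "DETEEE", "EETDEE", "EDTEEE", "EESEEE")))
  # the degeneracy comes from the T+D = E+S residue-pair composition identity
  expect_identical(peptide_formula("EESEEE"), peptide_formula("EETEED"))
  expect_equal(peptide_mass("EESEEE"), peptide_mass("EETEED"), tolerance = 1e-10)
})

test_that("isobaric grouping is a partition and an equivalence relation", {
  expect_equal(sum(hexa_classes$n_members), nrow(hexa))
  all_members <- unlist(hexa_classes$members)
  expect_equal(sort(all_members), sort(hexa$sequence))  # disjoint cover
  # same formula <=> same class (reflexive/symmetric/transitive by construction)
  cls_of <- rep(hexa_classes$class, hexa_classes$n_members)
  names(cls_of) <- all_members
  set.seed(3)
  for (i in 1:50) {
    p <- sample(hexa$sequence, 2)
    same_formula <- identical(peptide_formula(p[1]), peptide_formula(p[2]))
    expect_equal(cls_of[[p[1]]] == cls_of[[p[2]]], same_formula)
  }
  # single peptide -> one class of size 1
  one <- isobaric_classes(enumerate_library(library_spec(c("A", "A"))))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_members, 1)
  expect_error(isobaric_classes(hexa, policy = "mass", tol = -0.1))
})

test_that("exact-composition classes refine mass-tolerance classes", {
  for (eps in c(0.001, 0.1, 1)) {
    cls_tol <- isobaric_classes(hexa, policy = "mass", tol = eps)
    cls_of_tol <- rep(cls_tol$class, cls_tol$n_members)
    names(cls_of_tol) <- unlist(cls_tol$members)
    # every composition class must sit inside a single tolerance class
    for (m in hexa_classes$members)
      expect_equal(length(unique(cls_of_tol[m])), 1)
  }
})

test_that("peaks map to the right classes and unmatched peaks are flagged", {
  peaks <- data.frame(mz = c(750.28, 2000.0, 763.35),
                      intensity = c(100, 50, 80))
  asg <- assign_peaks(peaks, hexa_classes, tolerance = 0.5)
  hit750 <- asg[asg$mz == 750.28, ]
  expect_true(all(hit750$assigned))
  expect_equal(hit750$n_members, 6)
  expect_false(asg$assigned[asg$mz == 2000.0])
  hit763 <- asg[asg$mz == 763.35 & asg$assigned, ]
  i <- match(hit763$class, hexa_classes$class)
  expect_true(any(vapply(hexa_classes$members[i],
                         function(m) identical(m, "KETEEE"), TRUE)))
  expect_error(assign_peaks(peaks, hexa_classes, tolerance = 0))
})

test_that("enrichment ranks boosted classes first and excludes resin binders", {
  d <- generate_scenario("ms_pulldown", seed = 5)
  sc <- enrichment_score(d$data$library, d$data$eluent, d$data$control,
                         d$truth$classes)
  kept <- sc[sc$defined & !sc$unspecific, ]
  expect_equal(kept$key[1], d$truth$top_class_key)  # the x3 class wins
  expect_equal(kept$n_members[1], 6)
  # the control-boosted class is excluded no matter its eluent ratio
  ctrl_key <- names(d$truth$control_enriched)
  expect_true(sc$unspecific[match(ctrl_key, sc$key)])
  expect_false(ctrl_key %in% kept$key)
})

test_that("identical runs give unit enrichment and missing classes are flagged", {
  runs <- simulate_pulldown_peaks(hexa_classes, seed = 2,
                                  intensity_cv = 0, mz_sd = 0)
  sc <- enrichment_score(runs$library, runs$library, runs$library, hexa_classes)
  expect_true(all(abs(sc$enrichment[sc$defined] - 1) < 1e-12))
  # drop one class from the library run -> undefined ratio, flagged not fatal
  drop_key <- hexa_classes$key[1]
  ref <- vapply(hexa_classes$members[hexa_classes$key == drop_key],
                function(m) peptide_mass(m[1], adduct = "protonated"), 0)
  lib2 <- runs$library[abs(runs$library$mz - ref) > 0.5, ]
  sc2 <- enrichment_score(lib2, runs$library, runs$library, hexa_classes)
  row <- sc2[sc2$key == drop_key, ]
  expect_false(row$defined)
  expect_true(is.na(row$enrichment))
})
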