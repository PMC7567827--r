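# Peptide/fragment mass calculus and modified-sequence parsing.

test_that("neutral masses match frozen reference values", {
  expect_equal(peptide_neutral_mass("PEPTIDE"), 799.3599, tolerance = 0.001)
  expect_equal(peptide_neutral_mass("G"), 75.03203, tolerance = 0.0005)
  # fixed carbamidomethyl adds its printed delta
  expect_equal(peptide_neutral_mass("PEPTIC[CAM]K"),
               peptide_neutral_mass("PEPTICK") + 57.0214,
               tolerance = 0.001)
})

test_that("precursor m/z follows the charge formula", {
  expect_equal(precursor_mz("PEPTIDE", 2L), 400.6873, tolerance = 0.001)
  tab <- residue_mass_table()
  for (pep in c("ELVISK", "MGR", "WAY")) {
    expect_equal(precursor_mz(pep, 1L),
                 peptide_neutral_mass(pep) + tab$proton, tolerance = 1e-9)
  }
  expect_error(precursor_mz("PEPTIDE", 0), "charge")
})

test_that("fragment m/z matches frozen y1/b2 values and the whole-peptide identity", {
  expect_equal(fragment_mz("PEPTIDE", "y", 1L, 1L), 148.0604,
               tolerance = 0.001)
  expect_equal(fragment_mz("PEPTIDE", "b", 2L, 1L), 227.1026,
               tolerance = 0.001)
  expect_error(fragment_mz("PEPTIDE", "y", 7L, 1L), "ordinal")
  expect_error(fragment_mz("PEPTIDE", "a", 2L, 1L), "series")
})

test_that("modification notations normalize to the same parse", {
  forms <- c("PEPTIC(UniMod:4)K", "PEPTIC[Carbamidomethyl (C)]K",
             "PEPTIC[+57.0214]K", "PEPTIC[CAM]K")
  parses <- lapply(forms, parse_modified_sequence)
  for (p in parses) {
    expect_equal(p$stripped_sequence, "PEPTICK")
    expect_equal(p$mods$position, 6L)
    expect_equal(p$mods$name, "Carbamidomethyl")
    expect_true(p$verifiable)
  }
  # oxidation resolved by delta match within 0.001 Da
  p <- parse_modified_sequence("M[+15.9949]K")
  expect_equal(p$mods$name, "Oxidation")
  expect_equal(peptide_neutral_mass(p),
               peptide_neutral_mass("MK") + 15.9949, tolerance = 0.001)
})

test_that("malformed and unknown notations are handled per contract", {
  expect_error(parse_modified_sequence("PEP[TIDE"), "unbalanced")
  expect_error(parse_modified_sequence("PEPTIDE]"), "unbalanced")
  expect_error(parse_modified_sequence("P[CAM]K"), "not compatible")
  p <- parse_modified_sequence("PEPC[MadeUpMod]K")
  expect_false(p$verifiable)
  expect_equal(p$unknown_mods, "MadeUpMod")
  # unknown residues signal unverifiable, never crash
  expect_true(is.na(peptide_neutral_mass("PEPBZK")))
})

test_that("random peptide masses agree with the elemental-composition oracle", {
  set.seed(42)
  for (i in 1:100) {
    pep <- random_peptide(sample(5:25, 1))
    expect_equal(peptide_neutral_mass(pep), oracle_neutral_mass(pep),
                 tolerance = 1e-9)
  }
})

test_that("b/y complementarity holds as a closed-form identity", {
  tab <- residue_mass_table()
  set.seed(7)
  for (i in 1:20) {
    pep <- random_peptide(sample(6:18, 1))
    n <- nchar(pep)
    neutral <- peptide_neutral_mass(pep)
    for (ord in 1:(n - 1)) {
      b <- fragment_mz(pep, "b", ord, 1L)
      y <- fragment_mz(pep, "y", n - ord, 1L)
      expect_equal((b - tab$proton) + (y - tab$proton), neutral,
                   tolerance = 1e-9)
    }
  }
})

test_that("fragment m/z is strictly monotone in the ordinal", {
  set.seed(8)
  for (i in 1:10) {
    pep <- random_peptide(12)
    for (s in c("b", "y")) {
      mz <- vapply(1:11, function(o) fragment_mz(pep, s, o, 1L), numeric(1))
      expect_true(all(diff(mz) > 0))
    }
  }
})

test_that("whole-peptide y ion equals the singly charged precursor", {
  # y_n is not a fragment (ordinal capped at n-1); check via theory directly
  tab <- residue_mass_table()
  pep <- parse_modified_sequence("ELVISLIVESK")
  n <- nchar(pep$stripped_sequence)
  y_nm1 <- fragment_mz(pep, "y", n - 1L, 1L)
  first_res <- tab$residues[["E"]]
  expect_equal(y_nm1 + first_res, precursor_mz(pep, 1L), tolerance = 1e-9)
})

test_that("annotate_fragment matches, refuses and breaks ties as specified", {
  pep <- parse_modified_sequence("ELVISLIVEK")
  y3 <- fragment_mz(pep, "y", 3L, 1L)
  ann <- annotate_fragment(y3, pep, charge_max = 1L, tol = 0.05)
  expect_equal(ann[c("series", "ordinal")], list(series = "y", ordinal = 3L))
  expect_null(annotate_fragment(y3 + 0.3, pep, charge_max = 1L, tol = 0.05))

  # search for an observation equidistant between a b and a y ion with no
  # nearer neighbour; the tie must resolve to the y ion
  set.seed(13)
  found <- FALSE
  for (i in 1:200) {
    pp <- parse_modified_sequence(random_peptide(9))
    ions <- theoretical_ions(pp, charge_max = 1L)
    bs <- ions[ions$series == "b", ]
    ys <- ions[ions$series == "y", ]
    for (bi in seq_len(nrow(bs))) {
      for (yi in seq_len(nrow(ys))) {
        mid <- (bs$mz[bi] + ys$mz[yi]) / 2
        d <- abs(mid - ions$mz)
        half <- abs(bs$mz[bi] - ys$mz[yi]) / 2
        if (half > 1e-6 && half < 0.04 && sum(d <= half + 1e-9) == 2) {
          ann <- annotate_fragment(mid, pp, charge_max = 1L, tol = 0.05)
          expect_equal(ann$series, "y")
          expect_equal(ann$ordinal, ys$ordinal[yi])
          found <- TRUE
        }
      }
    }
    if (found) break
  }
  expect_true(found)
})
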