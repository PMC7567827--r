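# The 62-criterion assessment and its component statistics.

test_that("complexity counts distinct peptides, precursors and fragments", {
  lib <- make_hand_library()  # 2 peptides x {2+,3+} x 6 fragments
  cx <- complexity_stats(lib)
  expect_equal(cx$n_assays, 4L)
  expect_equal(cx$n_peptides, 2L)
  expect_equal(cx$n_precursor_ions, 4L)
  expect_equal(cx$n_fragment_ions, 24L)
  expect_equal(cx$n_proteins, 2L)
})

test_that("redundancy multiplies average fragments per precursor", {
  lib <- make_hand_library()
  raw <- make_redundant(lib, 7L, seed = 4)
  # as in raw (replicate-derived) libraries, fragments per *precursor ion*
  # rise ~7x while per-occurrence counts stay flat
  fpp <- function(l) complexity_stats(l)$n_fragment_ions /
    complexity_stats(l)$n_precursor_ions
  expect_equal(fpp(raw) / fpp(lib), 7, tolerance = 1e-9)
  merged <- merge_redundant(raw, n_top = 6L)
  expect_equal(nrow(merged$assays), nrow(lib$assays))
})

test_that("characteristics cover series, charge and digestion properties", {
  lib <- make_hand_library()
  ch <- characteristics_stats(lib)
  expect_equal(ch$pct_charge_2 + ch$pct_charge_3, 100)
  expect_equal(ch$pct_series_b + ch$pct_series_y + ch$pct_series_other, 100)
  expect_equal(ch$fragments_per_precursor_mean, 6)
  expect_equal(ch$pct_cterm_kr, 100)
  expect_equal(ch$pct_missed_cleavage_0, 100)
  expect_equal(ch$pct_all_positive_intensity, 100)

  ally <- lib
  ally$fragments$series <- "y"
  expect_equal(characteristics_stats(ally)$pct_series_y, 100)
})

test_that("modification statistics normalize across notations", {
  peptides <- c("AAAC[CAM]ELVISK", "AAAC(UniMod:4)ELVISK", "TENNESSEER")
  lib <- make_hand_library(peptides = peptides, charges = 2L)
  ms <- modification_stats(lib)
  expect_equal(ms$n_modification_types, 1L)  # both notations are one type
  expect_equal(ms$n_carbamidomethyl, 2L)
  expect_equal(ms$n_modified_assays, 2L)
  expect_equal(ms$pct_modified_assays, 100 * 2 / 3)

  plain <- make_hand_library()
  ms0 <- modification_stats(plain)
  expect_equal(ms0$n_modification_types, 0L)
  expect_equal(ms0$pct_modified_assays, 0)
})

test_that("completeness separates proteotypic, shared and unmapped peptides", {
  seqs <- c(P1 = "MMMKELVISLIVEKGGGR", P2 = "WWWRELVISLIVEKTTTK",
            P3 = "QQQFFFYYYK", P4 = "HHHGGGAAAR")
  idx <- build_proteome_index(seqs, digest_params(missed_cleavages = 0L,
                                                  length_range = c(5L, 30L)))
  lib <- make_hand_library(
    peptides = c("ELVISLIVEK",   # shared: P1 and P2
                 "QQQFFFYYYK",   # proteotypic: P3
                 "AAAAAAAAAK"),  # unmapped
    charges = 2L)
  cs <- completeness_stats(lib, idx)
  expect_equal(cs$proteome_size, 4L)
  expect_equal(cs$n_covered_proteins, 3L)
  expect_equal(cs$pct_proteome_coverage, 75)
  expect_equal(cs$pct_proteotypic, 50)  # 1 of 2 mapped peptides
  expect_equal(cs$pct_shared, 50)
  expect_equal(cs$n_unmapped_peptides, 1L)
})

test_that("target/decoy/mixed classification follows the cascade", {
  lib <- make_hand_library(
    peptides = c("ELVISLIVEK", "TENNESSEER", "GRACELANDK"),
    charges = 2L,
    proteins = c("sp|P1", "DECOY_sp|P2", "sp|P3;DECOY_sp|P4"))
  td <- classify_target_decoy(lib)
  expect_equal(td$class, c("target", "decoy", "mixed"))
  expect_equal(td$pct_target + td$pct_decoy + td$pct_mixed, 100,
               tolerance = 1e-9)
  # an explicit dialect decoy flag wins over accessions
  lib$assays$decoy <- c(TRUE, NA, NA)
  expect_equal(classify_target_decoy(lib)$class[1], "decoy")
})

test_that("delta-mass statistics recover exact and mixed offsets", {
  lib <- make_hand_library()   # theoretical m/z by construction
  dm <- delta_mass_stats(lib)
  expect_equal(dm$avg_fragment_delta, 0, tolerance = 1e-12)
  expect_equal(dm$avg_precursor_delta, 0, tolerance = 1e-12)
  expect_equal(dm$n_problem_assays, 0L)

  bad <- perturb_fragment_mz(lib, 0.02)
  # perturb half: restore the first two assays' fragments
  half <- bad
  first_two <- half$fragments$assay_id %in% c(1L, 2L)
  half$fragments$mz[first_two] <- lib$fragments$mz[first_two]
  dmh <- delta_mass_stats(half)
  expect_equal(dmh$avg_fragment_delta, 0.01, tolerance = 1e-9)
  expect_equal(dmh$n_fragment_errors, 12L)
  expect_equal(dmh$n_mass_error_assays, 2L)
})

test_that("unverifiable assays are counted, never crash the assessment", {
  lib <- make_hand_library(peptides = c("ELVISLIVEK", "TENNESSEER"))
  lib$assays$modified_sequence[2] <- "AAAX[Weird]ZZK"
  dm <- delta_mass_stats(lib)
  expect_equal(dm$n_unverifiable, 1L)
  expect_equal(dm$n_problem_assays, dm$n_mass_error_assays + 1L)
})

test_that("RT fit is exact on collinear pairs and matches the OLS oracle", {
  lib <- make_hand_library(peptides = c("ELVISLIVEK", "TENNESSEER",
                                        "GRACELANDK"),
                           rt = c(10, 20, 30))
  fit <- rt_correlation_fit(lib)
  expect_equal(fit$n_pairs, 3L)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)

  # noisy pairs: compare against a closed-form least-squares oracle
  set.seed(99)
  n <- 20
  peps <- replicate(n, random_peptide(10))
  lib2 <- make_hand_library(peptides = peps, rt = seq(5, 100, length.out = n))
  is3 <- lib2$assays$precursor_charge == 3L
  lib2$assays$rt[is3] <- lib2$assays$rt[is3] + rnorm(n, 0, 2)
  fit2 <- rt_correlation_fit(lib2)
  x <- lib2$assays$rt[!is3]; y <- lib2$assays$rt[is3]
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  r2 <- sum((alpha + beta * x - mean(y))^2) / sum((y - mean(y))^2)
  expect_equal(fit2$slope, beta, tolerance = 1e-9)
  expect_equal(fit2$intercept, alpha, tolerance = 1e-9)
  expect_equal(fit2$r_squared, r2, tolerance = 1e-9)

  short <- make_hand_library(peptides = c("ELVISLIVEK", "TENNESSEER"))
  expect_false(rt_correlation_fit(short)$evaluated)
})

test_that("conflict detection respects windows, overlaps and boundaries", {
  lib <- make_hand_library(peptides = "ELVISLIVEK", charges = 2L)
  lib$assays$precursor_mz <- 500.0
  lib$fragments$mz <- c(495.3, 600.2, 700, 800, 900, 1000)
  sch <- swath_scheme(490, 505)
  cf <- detect_conflicts(lib, sch)
  expect_equal(cf$n_conflict_fragments, 1L)
  expect_equal(cf$n_conflict_precursors, 1L)

  # overlapping windows: a fragment in either containing window conflicts
  sch2 <- swath_scheme(c(490, 499.5), c(500.5, 510))
  lib$fragments$mz[1] <- 499.8
  cf2 <- detect_conflicts(lib, sch2)
  expect_equal(cf2$n_conflict_fragments, 1L)

  # half-open convention: a fragment exactly at the window end is outside
  lib$fragments$mz[1] <- 505.0
  expect_equal(detect_conflicts(lib, sch)$n_conflict_fragments, 0L)
  # ... and exactly at the start is inside
  lib$fragments$mz[1] <- 490.0
  expect_equal(detect_conflicts(lib, sch)$n_conflict_fragments, 1L)

  # precursor outside every window is unverifiable for this criterion
  lib$assays$precursor_mz <- 1800
  cf3 <- detect_conflicts(lib, sch)
  expect_equal(cf3$n_unverifiable_precursors, 1L)
  expect_equal(cf3$n_conflict_fragments, 0L)
})

test_that("conflict detection agrees with the exhaustive scan", {
  cfg <- sim_config(seed = 17, n_proteins = 12L, peptides_per_protein = 4L)
  sch <- generate_swath_scheme(25, 400, 1250, overlap = 1, seed = 17)
  lib <- generate_library(cfg, generate_proteome(cfg))  # no DIA verification
  cf <- detect_conflicts(lib, sch)
  oracle <- oracle_conflicts(lib, sch)
  expect_equal(cf$conflict_assay_ids, oracle$conflict_ids)
  expect_equal(cf$n_conflict_fragments, oracle$n_frag)
})

test_that("assessment always yields 62 criteria and degrades gracefully", {
  lib <- make_hand_library(peptides = c("ELVISLIVEK", "TENNESSEER",
                                        "GRACELANDK"),
                           rt = c(10, 20, 30))
  rep1 <- assess(lib)
  expect_equal(nrow(rep1$criteria), 62L)
  expect_setequal(unique(rep1$criteria$category),
                  c("characteristics", "complexity", "completeness",
                    "correctness", "modifications"))
  # without scheme/proteome the dependent criteria are present, not omitted
  expect_equal(
    rep1$criteria$status[rep1$criteria$id == "n_conflict_precursors"],
    "not_evaluated")
  expect_true(all(rep1$criteria$status[rep1$criteria$category ==
                                         "completeness"] == "not_evaluated"))

  sch <- swath_scheme(400, 1250)
  idx <- build_proteome_index(c(P1 = "MMMKELVISLIVEKGGGR"))
  rep2 <- assess(lib, scheme = sch, proteome = idx)
  expect_true(all(rep2$criteria$status[rep2$criteria$category ==
                                         "completeness"] == "evaluated"))
  expect_equal(nrow(rep2$criteria), 62L)

  # determinism: identical inputs give identical reports
  expect_identical(assess(lib, scheme = sch), assess(lib, scheme = sch))

  # percentage conservation
  v <- function(id) criterion_value(rep2, id)
  expect_equal(v("pct_target") + v("pct_decoy") + v("pct_mixed"), 100,
               tolerance = 1e-9)
  expect_equal(v("pct_charge_1") + v("pct_charge_2") + v("pct_charge_3") +
                 v("pct_charge_4") + v("pct_charge_ge5"), 100,
               tolerance = 1e-9)
  expect_error(assess(subset_library(lib, integer(0))), "empty")
})

test_that("reports write as TSV with id/category/value/status columns", {
  lib <- make_hand_library()
  rep <- assess(lib)
  tf <- tempfile(fileext = ".tsv")
  write_report(rep, tf)
  got <- read.delim(tf)
  expect_equal(nrow(got), 62L)
  expect_equal(names(got), c("id", "category", "label", "value", "unit",
                             "status"))
})
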