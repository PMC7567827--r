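# Repair operations: mass correction, conflict filtering, top-N selection,
# decoy removal, redundancy merging, RT shifts, and the full pipeline.

test_that("mass correction restores theoretical m/z and is idempotent", {
  lib <- make_hand_library()
  bad <- perturb_fragment_mz(lib, 0.0064)
  fixed <- correct_masses(bad)
  expect_equal(delta_mass_stats(fixed)$avg_fragment_delta, 0,
               tolerance = 1e-9)
  twice <- correct_masses(fixed)
  expect_equal(twice$fragments$mz, fixed$fragments$mz, tolerance = 1e-12)
  expect_equal(nrow(attr(twice, "change_log")), 0L)
})

test_that("unverifiable assays pass through mass correction unchanged", {
  lib <- make_hand_library(peptides = c("ELVISLIVEK", "TENNESSEER"))
  lib$assays$modified_sequence[1:2] <- "AAAX[Weird]ZZK"  # both charges of pep 1
  bad <- perturb_fragment_mz(lib, 0.05)
  fixed <- correct_masses(bad)
  untouched <- fixed$fragments$assay_id %in% 1:2
  expect_equal(fixed$fragments$mz[untouched], bad$fragments$mz[untouched])
  log <- attr(fixed, "change_log")
  expect_true(all(c(1L, 2L) %in% log$assay_id[log$action == "skipped"]))
})

test_that("conflict filtering partitions the library exactly", {
  cfg <- sim_config(seed = 23, n_proteins = 15L)
  sch <- generate_swath_scheme(40, 400, 1250, seed = 23)
  lib <- generate_library(cfg, generate_proteome(cfg), scheme = sch)
  k <- round(0.1 * nrow(lib$assays))
  dirty <- inject_conflicts(lib, sch, 0.1, seed = 5)
  injected <- attr(dirty, "conflict_assay_ids")
  expect_length(injected, k)

  fc <- filter_conflicts(dirty, sch)
  expect_equal(sort(fc$problem_library$assays$modified_sequence),
               sort(dirty$assays$modified_sequence[
                 dirty$assays$assay_id %in% injected]))
  # partition conservation on assays and fragments
  expect_equal(nrow(fc$clean_library$assays) + nrow(fc$problem_library$assays),
               nrow(dirty$assays))
  expect_equal(nrow(fc$clean_library$fragments) +
                 nrow(fc$problem_library$fragments),
               nrow(dirty$fragments))
  # fixed point: the clean library re-checks to zero conflicts
  expect_equal(detect_conflicts(fc$clean_library, sch)$n_conflict_precursors,
               0L)
  expect_error(filter_conflicts(dirty, NULL), "scheme")
})

test_that("a conflict-free library filters to an empty problem library", {
  cfg <- sim_config(seed = 29, n_proteins = 10L)
  sch <- generate_swath_scheme(40, 400, 1250, seed = 29)
  lib <- generate_library(cfg, generate_proteome(cfg), scheme = sch)
  fc <- filter_conflicts(lib, sch)
  expect_equal(nrow(fc$problem_library$assays), 0L)
  expect_equal(library_multiset(fc$clean_library), library_multiset(lib))
})

test_that("top-N selection keeps the most intense fragments, ties by m/z", {
  lib <- make_hand_library(peptides = "ELVISLIVESK", charges = 2L,
                           n_frag = 10L)
  top <- limit_top_n_fragments(lib, 6L)
  expect_equal(nrow(top$fragments), 6L)
  kept <- top$fragments$intensity
  dropped <- setdiff(lib$fragments$intensity, kept)
  expect_true(min(kept) >= max(dropped))

  small <- make_hand_library()  # 6 fragments each
  expect_equal(library_multiset(limit_top_n_fragments(small, 6L)),
               library_multiset(small))

  # two fragments tied at the cut: the lower m/z wins
  tied <- make_hand_library(peptides = "ELVISLIVESK", charges = 2L,
                            n_frag = 4L)
  tied$fragments$intensity <- c(100, 50, 50, 10)
  keep2 <- limit_top_n_fragments(tied, 2L)
  expect_equal(nrow(keep2$fragments), 2L)
  tied_mz <- sort(tied$fragments$mz[tied$fragments$intensity == 50])
  expect_true(tied_mz[1] %in% keep2$fragments$mz)
  expect_false(tied_mz[2] %in% keep2$fragments$mz)
  expect_error(limit_top_n_fragments(lib, 0), ">= 1")
})

test_that("decoy removal restores a decoy-free library, keeping mixed assays", {
  cfg <- sim_config(seed = 31, n_proteins = 10L)
  pr <- generate_proteome(cfg)
  lib <- generate_library(cfg, pr)
  dirty <- inject_decoys(lib, 0.05, pr, seed = 6)
  expect_gt(classify_target_decoy(dirty)$pct_decoy, 0)
  clean <- remove_decoys(dirty)
  expect_equal(classify_target_decoy(clean)$pct_decoy, 0)
  expect_equal(nrow(clean$assays), nrow(lib$assays))

  # no decoys: identity
  same <- remove_decoys(lib)
  expect_equal(library_multiset(same), library_multiset(lib))

  # mixed assays are retained and logged
  mixed <- lib
  mixed$assays$protein_ids[1] <- "P1;DECOY_P2"
  kept <- remove_decoys(mixed)
  expect_equal(nrow(kept$assays), nrow(mixed$assays))
  log <- attr(kept, "change_log")
  expect_true(any(log$action == "retained"))
})

test_that("merging redundant occurrences sums intensities per fragment key", {
  lib <- make_hand_library()
  raw <- make_redundant(lib, 7L, seed = 8)
  merged <- merge_redundant(raw, n_top = 6L)
  expect_equal(nrow(merged$assays), nrow(lib$assays))

  # brute-force group-and-sum oracle over (precursor, fragment key)
  a <- raw$assays; f <- raw$fragments
  prec <- paste(a$modified_sequence, a$precursor_charge)[match(f$assay_id,
                                                               a$assay_id)]
  key <- paste(prec, f$series, f$ordinal, f$charge)
  want <- tapply(f$intensity, key, sum)
  am <- merged$assays; fm <- merged$fragments
  precm <- paste(am$modified_sequence, am$precursor_charge)[match(fm$assay_id,
                                                                  am$assay_id)]
  got <- fm$intensity
  names(got) <- paste(precm, fm$series, fm$ordinal, fm$charge)
  expect_equal(as.numeric(got[names(want)]), as.numeric(want),
               tolerance = 1e-9)

  # already-unique library with <= n_top fragments: identity
  expect_equal(library_multiset(merge_redundant(lib, 6L)),
               library_multiset(lib))
})

test_that("RT shifts move negative iRT scales into positive values", {
  lib <- make_hand_library(peptides = c("ELVISLIVEK", "TENNESSEER"),
                           rt = c(-51.0, 30))
  shifted <- shift_rt(lib, 51.6)
  expect_equal(min(shifted$assays$rt), 0.6, tolerance = 1e-9)
  back <- shift_rt(shifted, -51.6)
  expect_equal(back$assays$rt, lib$assays$rt, tolerance = 1e-9)
  expect_equal(shift_rt(lib, 0)$assays$rt, lib$assays$rt)
})

test_that("mass-correct then conflict-filter yields an error-free library", {
  cfg <- sim_config(seed = 37)
  sch <- generate_swath_scheme(60, 400, 1250, seed = 37)
  lib <- generate_library(cfg, generate_proteome(cfg), scheme = sch)
  defective <- inject_conflicts(perturb_fragment_mz(lib, 0.0064), sch,
                                fraction = 0.05, seed = 9)
  out <- repair_library(defective, sch)
  rep <- assess(out$clean_library, scheme = sch)
  expect_equal(criterion_value(rep, "avg_fragment_delta_mass"), 0,
               tolerance = 1e-9)
  expect_equal(criterion_value(rep, "n_conflict_precursors"), 0)
  expect_equal(criterion_value(rep, "n_problem_assays"), 0)
})
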