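# The 62-criterion library assessment: complexity, characteristics,
# modifications, completeness and correctness, including the four correctness
# diagnostics (target/decoy accounting, mass accuracy against theory,
# cross-charge RT correlation, DIA isolation-window conflict detection).

#' Assessment parameters
#'
#' @param tol_fragment Fragment mass-error tolerance in Da; a fragment ion
#'   whose |library - theoretical| m/z exceeds this counts as erroneous.
#' @param tol_precursor Precursor tolerance in Da, same role.
#' @param annotate_tol Tolerance used to annotate fragments that carry no
#'   ion-series columns against the theoretical b/y ladder.
#' @param fragment_charge_max Highest fragment charge enumerated for
#'   annotation.
#' @param digest [digest_params()] used for missed-cleavage statistics.
#' @param decoy_prefixes Accession prefixes marking decoy proteins.
#' @return An `assess_params` list.
#' @export
assess_params <- function(tol_fragment = 0.01, tol_precursor = 0.01,
                          annotate_tol = 0.1, fragment_charge_max = 2L,
                          digest = digest_params(),
                          decoy_prefixes = DECOY_PREFIXES_DEFAULT) {
  structure(list(tol_fragment = tol_fragment, tol_precursor = tol_precursor,
                 annotate_tol = annotate_tol,
                 fragment_charge_max = as.integer(fragment_charge_max),
                 digest = digest, decoy_prefixes = decoy_prefixes),
            class = "assess_params")
}

# Canonical rendering of a parsed peptide: "[Acetyl]-PEPC[Carbamidomethyl]K".
.canonical_modseq <- function(pep) {
  chars <- strsplit(pep$stripped_sequence, "", fixed = TRUE)[[1]]
  if (nrow(pep$mods) > 0) {
    for (k in seq_len(nrow(pep$mods))) {
      p <- pep$mods$position[k]
      chars[p] <- paste0(chars[p], "[", pep$mods$name[k], "]")
    }
  }
  out <- paste(chars, collapse = "")
  if (!is.null(pep$nterm)) out <- paste0("[", pep$nterm$name, "]-", out)
  out
}

# Parse every distinct modified sequence once; return per-assay annotations.
.parse_cache <- function(lib) {
  texts <- lib$assays$modified_sequence
  texts[is.na(texts)] <- ""
  uniq <- unique(texts)
  parsed <- lapply(uniq, function(t) {
    tryCatch(parse_modified_sequence(t), error = function(e) NULL)
  })
  info <- lapply(parsed, function(p) {
    if (is.null(p)) {
      list(ok = FALSE, stripped = NA_character_, canonical = NA_character_,
           mods = character(0))
    } else {
      mods <- p$mods$name
      if (!is.null(p$nterm)) mods <- c(p$nterm$name, mods)
      list(ok = p$verifiable, stripped = p$stripped_sequence,
           canonical = .canonical_modseq(p), mods = mods)
    }
  })
  map <- match(texts, uniq)
  list(
    parsed = parsed,
    map = map,
    ok = vapply(info, `[[`, logical(1), "ok")[map],
    stripped = vapply(info, `[[`, character(1), "stripped")[map],
    canonical = vapply(info, `[[`, character(1), "canonical")[map],
    mods = lapply(info, `[[`, "mods")[map]
  )
}

#' Library complexity counts
#'
#' @param lib A `spectral_library`.
#' @return Named list: assay count, distinct stripped and modified peptides,
#'   distinct precursor ions (modified sequence x charge), total fragment
#'   rows, distinct protein ids.
#' @export
complexity_stats <- function(lib) {
  a <- lib$assays
  prots <- unique(unlist(split_protein_ids(a$protein_ids)))
  list(
    n_assays = nrow(a),
    n_peptides = length(unique(a$stripped_sequence)),
    n_modified_peptides = length(unique(a$modified_sequence)),
    n_precursor_ions = nrow(unique(a[, c("modified_sequence",
                                         "precursor_charge")])),
    n_fragment_ions = nrow(lib$fragments),
    n_proteins = length(prots)
  )
}

#' Physical characteristics of precursor and fragment ions
#'
#' Charge distribution, precursor m/z and RT coverage, digestion properties
#' (peptide length, missed cleavages, tryptic C-terminus), fragments per
#' precursor, ion-series and fragment-charge composition, and intensity
#' distribution.
#'
#' @param lib A `spectral_library`.
#' @param digest [digest_params()] controlling the missed-cleavage rule.
#' @return Named list of 28 statistics.
#' @export
characteristics_stats <- function(lib, digest = digest_params()) {
  a <- lib$assays
  f <- lib$fragments
  n <- nrow(a)
  z <- a$precursor_charge
  pct <- function(x) 100 * sum(x, na.rm = TRUE) / n

  peptides <- unique(a$stripped_sequence)
  peptides <- peptides[!is.na(peptides)]
  plen <- nchar(peptides)
  mc <- count_missed_cleavages(peptides, digest$suppress_proline)
  np <- length(peptides)

  fpp <- tabulate(f$assay_id, nbins = n)
  has_rt <- !is.na(a$rt)

  rel_top <- vapply(split(f$intensity, f$assay_id), function(v) {
    s <- sum(v, na.rm = TRUE)
    if (s <= 0) return(NA_real_)
    100 * max(v, na.rm = TRUE) / s
  }, numeric(1))
  all_pos <- vapply(split(f$intensity, f$assay_id), function(v) {
    all(!is.na(v) & v > 0)
  }, logical(1))

  series <- ifelse(is.na(f$series), "other", f$series)
  list(
    pct_charge_1 = pct(z == 1), pct_charge_2 = pct(z == 2),
    pct_charge_3 = pct(z == 3), pct_charge_4 = pct(z == 4),
    pct_charge_ge5 = pct(z >= 5),
    precursor_mz_min = min(a$precursor_mz, na.rm = TRUE),
    precursor_mz_mean = mean(a$precursor_mz, na.rm = TRUE),
    precursor_mz_max = max(a$precursor_mz, na.rm = TRUE),
    pct_with_rt = pct(has_rt),
    rt_min = if (any(has_rt)) min(a$rt, na.rm = TRUE) else NA_real_,
    rt_max = if (any(has_rt)) max(a$rt, na.rm = TRUE) else NA_real_,
    peptide_length_min = min(plen),
    peptide_length_mean = mean(plen),
    peptide_length_max = max(plen),
    pct_missed_cleavage_0 = 100 * sum(mc == 0) / np,
    pct_missed_cleavage_1 = 100 * sum(mc == 1) / np,
    pct_missed_cleavage_ge2 = 100 * sum(mc >= 2) / np,
    pct_cterm_kr = 100 * sum(grepl("[KR]$", peptides)) / np,
    fragments_per_precursor_min = min(fpp),
    fragments_per_precursor_mean = mean(fpp),
    fragments_per_precursor_max = max(fpp),
    pct_series_b = 100 * sum(series == "b") / nrow(f),
    pct_series_y = 100 * sum(series == "y") / nrow(f),
    pct_series_other = 100 * sum(series == "other") / nrow(f),
    pct_fragment_charge_1 = 100 * sum(f$charge == 1, na.rm = TRUE) / nrow(f),
    pct_fragment_charge_ge2 = 100 * sum(f$charge >= 2, na.rm = TRUE) / nrow(f),
    top_fragment_mean_rel_intensity = mean(rel_top, na.rm = TRUE),
    pct_all_positive_intensity = 100 * sum(all_pos) / n
  )
}

#' Posttranslational-modification statistics
#'
#' Modification notations are normalized first, so `C[CAM]` and
#' `C(UniMod:4)` count as the same type.
#'
#' @param lib A `spectral_library`.
#' @return Named list: distinct modification types, modified-assay count and
#'   percentage, carbamidomethyl/oxidation/other site counts.
#' @export
modification_stats <- function(lib) {
  pc <- .parse_cache(lib)
  all_mods <- unlist(pc$mods)
  n_modified <- sum(vapply(pc$mods, length, integer(1)) > 0)
  list(
    n_modification_types = length(unique(all_mods)),
    n_modified_assays = n_modified,
    pct_modified_assays = 100 * n_modified / nrow(lib$assays),
    n_carbamidomethyl = sum(all_mods == "Carbamidomethyl"),
    n_oxidation = sum(all_mods == "Oxidation"),
    n_other_modifications = sum(!all_mods %in%
                                  c("Carbamidomethyl", "Oxidation"))
  )
}

#' Proteome-coverage and proteotypicity statistics
#'
#' A library peptide is proteotypic when it maps to exactly one target
#' protein of the digest index, shared when it maps to several; peptides
#' absent from the in-silico digest are counted unmapped.
#'
#' @param lib A `spectral_library`.
#' @param proteome A `proteome_index` from [build_proteome_index()].
#' @return Named list of 8 coverage statistics.
#' @export
completeness_stats <- function(lib, proteome) {
  stopifnot(inherits(proteome, "proteome_index"))
  peptides <- unique(lib$assays$stripped_sequence)
  peptides <- peptides[!is.na(peptides)]
  hits <- proteome$peptide_map[peptides]
  n_targets <- vapply(hits, function(h) {
    if (is.null(h)) 0L else sum(!proteome$accession_decoy[h])
  }, integer(1))
  mapped <- n_targets > 0
  covered <- unique(unlist(lapply(hits[mapped], function(h) {
    h[!proteome$accession_decoy[h]]
  })))
  pep_per_prot <- table(unlist(lapply(hits[mapped], function(h) {
    unique(h[!proteome$accession_decoy[h]])
  })))
  list(
    proteome_size = proteome$proteome_size,
    n_covered_proteins = length(covered),
    pct_proteome_coverage = 100 * length(covered) / proteome$proteome_size,
    pct_proteotypic = if (any(mapped)) 100 * sum(n_targets == 1) / sum(mapped)
                      else NA_real_,
    pct_shared = if (any(mapped)) 100 * sum(n_targets > 1) / sum(mapped)
                 else NA_real_,
    mean_peptides_per_covered_protein =
      if (length(covered)) mean(as.numeric(pep_per_prot)) else NA_real_,
    n_single_peptide_proteins = sum(pep_per_prot == 1),
    n_unmapped_peptides = sum(!mapped)
  )
}

#' Classify assays as target, decoy or mixed
#'
#' Classification uses, in order: the dialect's decoy column when present for
#' an assay; decoy accession prefixes; the target/decoy class of accessions
#' in a supplied proteome index. An assay mapping to both target and decoy
#' proteins is "mixed".
#'
#' @param lib A `spectral_library`.
#' @param proteome Optional `proteome_index`.
#' @param decoy_prefixes Accession prefixes marking decoys.
#' @return List with `pct_target`, `pct_decoy`, `pct_mixed` (summing to 100)
#'   and the per-assay `class` factor.
#' @export
classify_target_decoy <- function(lib, proteome = NULL,
                                  decoy_prefixes = DECOY_PREFIXES_DEFAULT) {
  a <- lib$assays
  rx <- paste0("^(", paste(decoy_prefixes, collapse = "|"), ")")
  prot_lists <- split_protein_ids(a$protein_ids)
  cls <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (!is.na(a$decoy[i])) {
      cls[i] <- if (a$decoy[i]) "decoy" else "target"
      next
    }
    prots <- prot_lists[[i]]
    if (length(prots) == 0L) { cls[i] <- "target"; next }
    is_dec <- grepl(rx, prots)
    if (!is.null(proteome)) {
      known <- prots %in% names(proteome$accession_decoy)
      is_dec[known] <- is_dec[known] |
        proteome$accession_decoy[prots[known]]
    }
    cls[i] <- if (all(is_dec)) "decoy" else if (any(is_dec)) "mixed"
              else "target"
  }
  n <- length(cls)
  list(pct_target = 100 * sum(cls == "target") / n,
       pct_decoy = 100 * sum(cls == "decoy") / n,
       pct_mixed = 100 * sum(cls == "mixed") / n,
       class = cls)
}

#' Mass accuracy of library m/z against theory
#'
#' Computes the signed difference (library minus theoretical) for every
#' verifiable precursor and fragment ion, the signed averages, and counts of
#' ions above tolerance. Fragments without ion-series columns are annotated
#' against the theoretical b/y ladder within `params$annotate_tol`; fragments
#' matching no b/y ion are scored "other" and excluded from averaging.
#' Assays whose sequence cannot be parsed or contains non-standard residues
#' are unverifiable; problem assays are the disjoint union of mass-error and
#' unverifiable assays.
#'
#' @param lib A `spectral_library`.
#' @param params [assess_params()].
#' @return A `delta_mass_stats` list; see Details.
#' @export
delta_mass_stats <- function(lib, params = assess_params()) {
  a <- lib$assays
  f <- lib$fragments
  pc <- .parse_cache(lib)
  n <- nrow(a)
  prec_delta <- rep(NA_real_, n)
  frag_idx_by_assay <- split(seq_len(nrow(f)), f$assay_id)
  frag_delta <- rep(NA_real_, nrow(f))
  frag_verifiable <- rep(FALSE, nrow(f))
  unverifiable <- !pc$ok

  for (i in seq_len(n)) {
    if (unverifiable[i]) next
    pep <- pc$parsed[[pc$map[i]]]
    plen <- nchar(pep$stripped_sequence)
    idx <- frag_idx_by_assay[[as.character(a$assay_id[i])]]
    th_prec <- precursor_mz(pep, a$precursor_charge[i])
    prec_delta[i] <- a$precursor_mz[i] - th_prec
    if (is.null(idx)) next
    zmax <- max(params$fragment_charge_max, f$charge[idx], na.rm = TRUE)
    ladder <- theoretical_ions(pep, charge_max = zmax)
    if (nrow(ladder) == 0L) next
    key <- paste(ladder$series, ladder$ordinal, ladder$charge)
    for (j in idx) {
      s <- f$series[j]
      o <- f$ordinal[j]
      z <- f$charge[j]
      if (!is.na(s) && s %in% c("b", "y") && !is.na(o) &&
          o >= 1 && o <= plen - 1 && !is.na(z) && z >= 1) {
        hit <- match(paste(s, o, z), key)
        if (!is.na(hit)) {
          frag_delta[j] <- f$mz[j] - ladder$mz[hit]
          frag_verifiable[j] <- TRUE
        }
      } else {
        ann <- annotate_fragment(f$mz[j], pep,
                                 charge_max = params$fragment_charge_max,
                                 tol = params$annotate_tol)
        if (!is.null(ann)) {
          frag_delta[j] <- ann$delta
          frag_verifiable[j] <- TRUE
        }
      }
    }
  }

  frag_err <- frag_verifiable & abs(frag_delta) > params$tol_fragment
  prec_err <- !is.na(prec_delta) & abs(prec_delta) > params$tol_precursor
  err_assays <- unique(c(a$assay_id[prec_err],
                         f$assay_id[which(frag_err)]))
  err_assays <- setdiff(err_assays, a$assay_id[unverifiable])
  structure(list(
    avg_precursor_delta = mean(prec_delta, na.rm = TRUE),
    avg_fragment_delta = mean(frag_delta[frag_verifiable]),
    n_precursor_errors = sum(prec_err),
    n_fragment_errors = sum(frag_err, na.rm = TRUE),
    n_unverifiable = sum(unverifiable),
    n_mass_error_assays = length(err_assays),
    n_problem_assays = length(err_assays) + sum(unverifiable),
    mass_error_assay_ids = sort(err_assays),
    unverifiable_assay_ids = a$assay_id[unverifiable],
    precursor_deltas = prec_delta,
    fragment_deltas = ifelse(frag_verifiable, frag_delta, NA_real_)
  ), class = "delta_mass_stats")
}

#' Cross-charge retention-time correlation
#'
#' Ordinary least-squares fit of RT at 3+ against RT at 2+ over peptides
#' (same modified sequence) observed at both charge states; duplicate
#' occurrences resolve to the first. A good library shows R-squared near 1,
#' since both charge states of a peptide co-elute.
#'
#' @param lib A `spectral_library`.
#' @return An `rt_fit` list: `n_pairs`, `slope`, `intercept`, `r_squared`,
#'   `evaluated`, and the paired RT vectors `rt2`/`rt3`. Fewer than 3 pairs
#'   (or degenerate RT spread) gives `evaluated = FALSE`.
#' @export
rt_correlation_fit <- function(lib) {
  a <- lib$assays[!is.na(lib$assays$rt), , drop = FALSE]
  a2 <- a[a$precursor_charge == 2L, , drop = FALSE]
  a3 <- a[a$precursor_charge == 3L, , drop = FALSE]
  a2 <- a2[!duplicated(a2$modified_sequence), , drop = FALSE]
  a3 <- a3[!duplicated(a3$modified_sequence), , drop = FALSE]
  common <- intersect(a2$modified_sequence, a3$modified_sequence)
  rt2 <- a2$rt[match(common, a2$modified_sequence)]
  rt3 <- a3$rt[match(common, a3$modified_sequence)]
  out <- list(n_pairs = length(common), slope = NA_real_,
              intercept = NA_real_, r_squared = NA_real_,
              evaluated = FALSE, rt2 = rt2, rt3 = rt3)
  if (length(common) >= 3L && stats::var(rt2) > 0) {
    fit <- stats::lm(rt3 ~ rt2)
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
    tss <- sum((rt3 - mean(rt3))^2)
    out$r_squared <- if (tss == 0) 1 else
      1 - sum(stats::residuals(fit)^2) / tss
    out$evaluated <- TRUE
  }
  structure(out, class = "rt_fit")
}

#' Detect DIA isolation-window conflicts
#'
#' A fragment ion conflicts when its m/z lies inside any isolation window
#' `[start, end)` that also contains its own precursor's m/z: residual
#' un-fragmented precursor signal in that window can contaminate the
#' fragment's extracted intensity. Precursors outside every window cannot be
#' verified against the scheme and are reported separately.
#'
#' @param lib A `spectral_library`.
#' @param scheme A `swath_scheme`.
#' @return A `conflict_stats` list: `n_conflict_precursors`,
#'   `n_conflict_fragments`, `conflict_assay_ids`, `conflict_index`
#'   (data frame of offending fragments), `n_unverifiable_precursors`.
#' @export
detect_conflicts <- function(lib, scheme) {
  stopifnot(inherits(scheme, "swath_scheme"))
  a <- lib$assays
  f <- lib$fragments
  assay_row <- match(f$assay_id, a$assay_id)
  frag_conflict <- rep(FALSE, nrow(f))
  prec_in_any <- rep(FALSE, nrow(a))
  for (w in seq_len(nrow(scheme))) {
    s <- scheme$start[w]; e <- scheme$end[w]
    in_w_assay <- !is.na(a$precursor_mz) & a$precursor_mz >= s &
      a$precursor_mz < e
    prec_in_any <- prec_in_any | in_w_assay
    frag_conflict <- frag_conflict |
      (in_w_assay[assay_row] & !is.na(f$mz) & f$mz >= s & f$mz < e)
  }
  conflict_ids <- sort(unique(f$assay_id[frag_conflict]))
  structure(list(
    n_conflict_precursors = length(conflict_ids),
    n_conflict_fragments = sum(frag_conflict),
    conflict_assay_ids = conflict_ids,
    conflict_index = data.frame(
      assay_id = f$assay_id[frag_conflict],
      fragment_mz = f$mz[frag_conflict],
      stringsAsFactors = FALSE),
    n_unverifiable_precursors = sum(!prec_in_any),
    unverifiable_assay_ids = a$assay_id[!prec_in_any]
  ), class = "conflict_stats")
}

# The fixed 62-criterion registry: id, category, label, unit.
.criteria_registry <- function() {
  reg <- function(id, category, label, unit) {
    data.frame(id = id, category = category, label = label, unit = unit,
               stringsAsFactors = FALSE)
  }
  rbind(
    reg("n_assays", "complexity", "Assays (precursor occurrences)", "count"),
    reg("n_peptides", "complexity", "Distinct stripped peptides", "count"),
    reg("n_modified_peptides", "complexity", "Distinct modified peptides",
        "count"),
    reg("n_precursor_ions", "complexity",
        "Distinct precursor ions (modified peptide x charge)", "count"),
    reg("n_fragment_ions", "complexity", "Fragment ions (transitions)",
        "count"),
    reg("n_proteins", "complexity", "Distinct protein ids", "count"),
    reg("pct_charge_1", "characteristics", "Precursor charge 1+", "%"),
    reg("pct_charge_2", "characteristics", "Precursor charge 2+", "%"),
    reg("pct_charge_3", "characteristics", "Precursor charge 3+", "%"),
    reg("pct_charge_4", "characteristics", "Precursor charge 4+", "%"),
    reg("pct_charge_ge5", "characteristics", "Precursor charge >=5+", "%"),
    reg("precursor_mz_min", "characteristics", "Precursor m/z minimum", "Th"),
    reg("precursor_mz_mean", "characteristics", "Precursor m/z mean", "Th"),
    reg("precursor_mz_max", "characteristics", "Precursor m/z maximum", "Th"),
    reg("pct_with_rt", "characteristics", "Assays with retention time", "%"),
    reg("rt_min", "characteristics", "Retention time minimum", "RT"),
    reg("rt_max", "characteristics", "Retention time maximum", "RT"),
    reg("peptide_length_min", "characteristics", "Peptide length minimum",
        "residues"),
    reg("peptide_length_mean", "characteristics", "Peptide length mean",
        "residues"),
    reg("peptide_length_max", "characteristics", "Peptide length maximum",
        "residues"),
    reg("pct_missed_cleavage_0", "characteristics", "Peptides with 0 missed cleavages", "%"),
    reg("pct_missed_cleavage_1", "characteristics", "Peptides with 1 missed cleavage", "%"),
    reg("pct_missed_cleavage_ge2", "characteristics", "Peptides with >=2 missed cleavages", "%"),
    reg("pct_cterm_kr", "characteristics", "Peptides ending in K or R", "%"),
    reg("fragments_per_precursor_min", "characteristics",
        "Fragments per precursor minimum", "count"),
    reg("fragments_per_precursor_mean", "characteristics",
        "Fragments per precursor mean", "count"),
    reg("fragments_per_precursor_max", "characteristics",
        "Fragments per precursor maximum", "count"),
    reg("pct_series_b", "characteristics", "Fragment ions in b series", "%"),
    reg("pct_series_y", "characteristics", "Fragment ions in y series", "%"),
    reg("pct_series_other", "characteristics",
        "Fragment ions in other/unknown series", "%"),
    reg("pct_fragment_charge_1", "characteristics", "Fragment charge 1+", "%"),
    reg("pct_fragment_charge_ge2", "characteristics",
        "Fragment charge >=2+", "%"),
    reg("top_fragment_mean_rel_intensity", "characteristics",
        "Mean relative intensity of top fragment", "%"),
    reg("pct_all_positive_intensity", "characteristics",
        "Precursors with all-positive fragment intensities", "%"),
    reg("n_modification_types", "modifications",
        "Distinct modification types", "count"),
    reg("n_modified_assays", "modifications", "Modified assays", "count"),
    reg("pct_modified_assays", "modifications", "Modified assays", "%"),
    reg("n_carbamidomethyl", "modifications", "Carbamidomethyl sites",
        "count"),
    reg("n_oxidation", "modifications", "Oxidation sites", "count"),
    reg("n_other_modifications", "modifications", "Other modification sites",
        "count"),
    reg("proteome_size", "completeness", "Target proteome size", "count"),
    reg("n_covered_proteins", "completeness", "Proteins covered by library",
        "count"),
    reg("pct_proteome_coverage", "completeness", "Proteome coverage", "%"),
    reg("pct_proteotypic", "completeness", "Proteotypic peptides", "%"),
    reg("pct_shared", "completeness", "Shared peptides", "%"),
    reg("mean_peptides_per_covered_protein", "completeness",
        "Mean peptides per covered protein", "count"),
    reg("n_single_peptide_proteins", "completeness",
        "Proteins covered by a single peptide", "count"),
    reg("n_unmapped_peptides", "completeness",
        "Library peptides absent from the digest", "count"),
    reg("pct_target", "correctness", "Target assays", "%"),
    reg("pct_decoy", "correctness", "Decoy assays", "%"),
    reg("pct_mixed", "correctness", "Mixed (target+decoy) assays", "%"),
    reg("avg_precursor_delta_mass", "correctness",
        "Average precursor delta mass (library - theoretical)", "Da"),
    reg("avg_fragment_delta_mass", "correctness",
        "Average fragment delta mass (library - theoretical)", "Da"),
    reg("n_mass_error_assays", "correctness",
        "Assays with a mass error above tolerance", "count"),
    reg("n_unverifiable_assays", "correctness",
        "Assays that cannot be verified", "count"),
    reg("n_problem_assays", "correctness",
        "Problem assays (mass errors + unverifiable)", "count"),
    reg("rt_fit_n_pairs", "correctness", "Peptides with 2+/3+ RT pairs",
        "count"),
    reg("rt_fit_slope", "correctness", "RT fit slope (3+ vs 2+)", "ratio"),
    reg("rt_fit_intercept", "correctness", "RT fit intercept", "RT"),
    reg("rt_fit_r_squared", "correctness", "RT fit R-squared", "ratio"),
    reg("n_conflict_precursors", "correctness",
        "Precursors with >=1 conflict fragment", "count"),
    reg("n_conflict_fragments", "correctness",
        "Fragment ions in the precursor's DIA bin", "count")
  )
}

#' Assess a spectral library against the 62-criterion registry
#'
#' Evaluates every criterion of the registry; criteria requiring an absent
#' optional input (SWATH scheme for conflict detection, proteome index for
#' completeness) are reported with status `not_evaluated`, never omitted.
#' The result is deterministic for fixed inputs.
#'
#' @param lib A `spectral_library`.
#' @param scheme Optional `swath_scheme`.
#' @param proteome Optional `proteome_index`.
#' @param params [assess_params()].
#' @return An `assessment_report`: data frame `criteria` with exactly 62 rows
#'   (`id`, `category`, `label`, `value`, `unit`, `status`) plus a `details`
#'   list holding the underlying statistics objects.
#' @export
assess <- function(lib, scheme = NULL, proteome = NULL,
                   params = assess_params()) {
  stopifnot(inherits(lib, "spectral_library"))
  if (nrow(lib$assays) == 0L) stop("empty library")
  reg <- .criteria_registry()
  vals <- stats::setNames(rep(NA_real_, nrow(reg)), reg$id)
  status <- stats::setNames(rep("evaluated", nrow(reg)), reg$id)
  set <- function(x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (nm %in% names(vals)) vals[nm] <<- if (is.na(v)) NA_real_ else v
    }
  }
  set(complexity_stats(lib))
  ch <- characteristics_stats(lib, params$digest)
  set(ch)
  if (is.na(ch$rt_min)) status[c("rt_min", "rt_max")] <- "not_evaluated"
  set(modification_stats(lib))

  comp_ids <- reg$id[reg$category == "completeness"]
  if (!is.null(proteome)) {
    set(completeness_stats(lib, proteome))
  } else {
    status[comp_ids] <- "not_evaluated"
  }

  td <- classify_target_decoy(lib, proteome, params$decoy_prefixes)
  set(td[c("pct_target", "pct_decoy", "pct_mixed")])

  dm <- delta_mass_stats(lib, params)
  rt <- rt_correlation_fit(lib)
  set(list(avg_precursor_delta_mass = dm$avg_precursor_delta,
           avg_fragment_delta_mass = dm$avg_fragment_delta,
           n_mass_error_assays = dm$n_mass_error_assays,
           rt_fit_n_pairs = rt$n_pairs))
  if (rt$evaluated) {
    set(list(rt_fit_slope = rt$slope, rt_fit_intercept = rt$intercept,
             rt_fit_r_squared = rt$r_squared))
  } else {
    status[c("rt_fit_slope", "rt_fit_intercept", "rt_fit_r_squared")] <-
      "not_evaluated"
  }

  cf <- NULL
  n_unverifiable <- dm$n_unverifiable
  unverifiable_ids <- dm$unverifiable_assay_ids
  if (!is.null(scheme)) {
    cf <- detect_conflicts(lib, scheme)
    set(list(n_conflict_precursors = cf$n_conflict_precursors,
             n_conflict_fragments = cf$n_conflict_fragments))
    unverifiable_ids <- union(unverifiable_ids, cf$unverifiable_assay_ids)
    n_unverifiable <- length(unverifiable_ids)
  } else {
    status[c("n_conflict_precursors", "n_conflict_fragments")] <-
      "not_evaluated"
  }
  mass_error_ids <- setdiff(dm$mass_error_assay_ids, unverifiable_ids)
  set(list(n_unverifiable_assays = n_unverifiable,
           n_problem_assays = length(mass_error_ids) + n_unverifiable))

  criteria <- cbind(reg,
                    value = unname(vals[reg$id]),
                    status = unname(status[reg$id]),
                    stringsAsFactors = FALSE)
  criteria$status[is.na(criteria$value) &
                    criteria$status == "evaluated"] <- "not_evaluated"
  criteria <- criteria[, c("id", "category", "label", "value", "unit",
                           "status")]
  stopifnot(nrow(criteria) == 62L)
  structure(list(
    criteria = criteria,
    details = list(delta_mass = dm, rt_fit = rt, conflicts = cf,
                   target_decoy = td, characteristics = ch),
    inputs = list(has_scheme = !is.null(scheme),
                  has_proteome = !is.null(proteome)),
    params = params
  ), class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("assessment_report: 62 criteria in 5 categories\n")
  for (cat_name in unique(x$criteria$category)) {
    sub <- x$criteria[x$criteria$category == cat_name, ]
    cat(sprintf("  %s: %d criteria (%d evaluated)\n", cat_name, nrow(sub),
                sum(sub$status == "evaluated")))
  }
  invisible(x)
}

#' Extract one criterion value from a report
#'
#' @param report An `assessment_report`.
#' @param id Criterion id.
#' @return The numeric value (NA when not evaluated).
#' @export
criterion_value <- function(report, id) {
  stopifnot(inherits(report, "assessment_report"))
  i <- match(id, report$criteria$id)
  if (is.na(i)) stop("unknown criterion id: ", id)
  report$criteria$value[i]
}

#' Write an assessment report as TSV
#'
#' @param report An `assessment_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- report$criteria
  df$value <- ifelse(is.na(df$value), "", sprintf("%.6g", df$value))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
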