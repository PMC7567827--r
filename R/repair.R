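# Library repair: rewriting m/z to theoretical values, segregating conflict
# assays into clean/problem libraries, and hygiene operations (top-N fragment
# selection, decoy removal, redundancy merging, RT shifts).

.empty_change_log <- function() {
  data.frame(assay_id = integer(0), action = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

.log_change <- function(log, assay_id, action, detail) {
  rbind(log, data.frame(assay_id = assay_id, action = action,
                        detail = detail, stringsAsFactors = FALSE))
}

#' Rewrite library m/z to theoretical values
#'
#' Replaces fragment and/or precursor m/z by their theoretical monoisotopic
#' values. Fragments carrying b/y series columns are recomputed directly;
#' unlabeled fragments are annotated against the theoretical ladder within
#' `params$annotate_tol` and rewritten only when a match exists. Assays that
#' cannot be verified (unparseable sequence, non-standard residues) pass
#' through unchanged and are logged. The operation is idempotent.
#'
#' @param lib A `spectral_library`.
#' @param scope `"fragments"` (default), `"precursors"` or `"both"`.
#' @param params [assess_params()] (for the annotation tolerance).
#' @return A `spectral_library` with attribute `change_log`.
#' @export
correct_masses <- function(lib, scope = c("fragments", "precursors", "both"),
                           params = assess_params()) {
  scope <- match.arg(scope)
  a <- lib$assays
  f <- lib$fragments
  pc <- .parse_cache(lib)
  log <- .empty_change_log()
  frag_idx_by_assay <- split(seq_len(nrow(f)), f$assay_id)
  for (i in seq_len(nrow(a))) {
    if (!pc$ok[i]) {
      log <- .log_change(log, a$assay_id[i], "skipped",
                         "unverifiable sequence")
      next
    }
    pep <- pc$parsed[[pc$map[i]]]
    plen <- nchar(pep$stripped_sequence)
    if (scope %in% c("precursors", "both")) {
      th <- precursor_mz(pep, a$precursor_charge[i])
      if (abs(a$precursor_mz[i] - th) > 1e-9) {
        log <- .log_change(log, a$assay_id[i], "precursor_mz_corrected",
                           sprintf("%.6f -> %.6f", a$precursor_mz[i], th))
        a$precursor_mz[i] <- th
      }
    }
    if (scope %in% c("fragments", "both")) {
      idx <- frag_idx_by_assay[[as.character(a$assay_id[i])]]
      if (is.null(idx)) next
      zmax <- max(params$fragment_charge_max, f$charge[idx], na.rm = TRUE)
      ladder <- theoretical_ions(pep, charge_max = zmax)
      key <- paste(ladder$series, ladder$ordinal, ladder$charge)
      for (j in idx) {
        s <- f$series[j]; o <- f$ordinal[j]; z <- f$charge[j]
        th <- NA_real_
        if (!is.na(s) && s %in% c("b", "y") && !is.na(o) &&
            o >= 1 && o <= plen - 1 && !is.na(z) && z >= 1) {
          hit <- match(paste(s, o, z), key)
          if (!is.na(hit)) th <- ladder$mz[hit]
        } else {
          ann <- annotate_fragment(f$mz[j], pep,
                                   charge_max = params$fragment_charge_max,
                                   tol = params$annotate_tol)
          if (!is.null(ann)) {
            th <- ann$mz
            f$series[j] <- ann$series
            f$ordinal[j] <- ann$ordinal
            f$charge[j] <- ann$charge
          }
        }
        if (is.na(th)) {
          log <- .log_change(log, a$assay_id[i], "fragment_unmatched",
                             sprintf("mz %.6f has no b/y match", f$mz[j]))
        } else if (abs(f$mz[j] - th) > 1e-9) {
          log <- .log_change(log, a$assay_id[i], "fragment_mz_corrected",
                             sprintf("%.6f -> %.6f", f$mz[j], th))
          f$mz[j] <- th
        }
      }
    }
  }
  out <- spectral_library(a, f, dialect = lib$dialect,
                          source_columns = lib$source_columns,
                          rejected = lib$rejected,
                          n_input_rows = lib$n_input_rows)
  attr(out, "change_log") <- log
  out
}

#' Segregate conflict assays into problem and clean libraries
#'
#' Assays with at least one conflict fragment (per [detect_conflicts()]) are
#' moved whole into the problem library; all others form the clean library,
#' which yields zero conflicts on re-check. With
#' `mode = "drop_fragments"` only the offending fragments are removed
#' instead (assays left without fragments are then moved to the problem
#' library).
#'
#' @param lib A `spectral_library`.
#' @param scheme A `swath_scheme` (required).
#' @param mode `"assays"` (default) or `"drop_fragments"`.
#' @return A `repair_outcome` list: `clean_library`, `problem_library`,
#'   `conflicts` (the `conflict_stats`), `change_log`.
#' @export
filter_conflicts <- function(lib, scheme, mode = c("assays", "drop_fragments")) {
  if (missing(scheme) || is.null(scheme))
    stop("a SWATH scheme is required for conflict filtering")
  mode <- match.arg(mode)
  cf <- detect_conflicts(lib, scheme)
  log <- .empty_change_log()
  if (mode == "assays") {
    bad <- cf$conflict_assay_ids
    good <- setdiff(lib$assays$assay_id, bad)
    for (id in bad)
      log <- .log_change(log, id, "moved_to_problem", "conflict fragment")
    outcome <- list(clean_library = subset_library(lib, good),
                    problem_library = subset_library(lib, bad),
                    conflicts = cf, change_log = log)
  } else {
    f <- lib$fragments
    drop <- rep(FALSE, nrow(f))
    key <- paste(cf$conflict_index$assay_id, cf$conflict_index$fragment_mz)
    drop <- paste(f$assay_id, f$mz) %in% key
    f2 <- f[!drop, , drop = FALSE]
    keep_ids <- unique(f2$assay_id)
    empty <- setdiff(lib$assays$assay_id, keep_ids)
    lib2 <- spectral_library(lib$assays, f2, dialect = lib$dialect,
                             source_columns = lib$source_columns,
                             n_input_rows = nrow(f2))
    for (id in empty)
      log <- .log_change(log, id, "moved_to_problem", "all fragments conflict")
    outcome <- list(clean_library = subset_library(lib2, keep_ids),
                    problem_library = subset_library(lib, empty),
                    conflicts = cf, change_log = log)
  }
  structure(outcome, class = "repair_outcome")
}

#' @export
print.repair_outcome <- function(x, ...) {
  cat(sprintf("repair_outcome: %d clean assays, %d problem assays\n",
              nrow(x$clean_library$assays), nrow(x$problem_library$assays)))
  invisible(x)
}

#' Keep the top-N fragments per precursor
#'
#' Fragments are ranked by decreasing intensity, ties broken by lower m/z;
#' assays with at most `n` fragments are unchanged.
#'
#' @param lib A `spectral_library`.
#' @param n Fragments to keep per assay (>= 1).
#' @return A `spectral_library`.
#' @export
limit_top_n_fragments <- function(lib, n = 6L) {
  if (n < 1) stop("n must be >= 1")
  f <- lib$fragments
  keep <- unlist(lapply(split(seq_len(nrow(f)), f$assay_id), function(idx) {
    if (length(idx) <= n) return(idx)
    ord <- order(-f$intensity[idx], f$mz[idx])
    idx[ord[seq_len(n)]]
  }), use.names = FALSE)
  keep <- sort(keep)
  spectral_library(lib$assays, f[keep, , drop = FALSE],
                   dialect = lib$dialect,
                   source_columns = lib$source_columns,
                   n_input_rows = length(keep))
}

#' Remove decoy assays
#'
#' Assays classed decoy by [classify_target_decoy()] are removed; mixed
#' assays are retained and logged.
#'
#' @param lib A `spectral_library`.
#' @param proteome Optional `proteome_index` supporting classification.
#' @param decoy_prefixes Accession prefixes marking decoys.
#' @return A `spectral_library` with attribute `change_log`.
#' @export
remove_decoys <- function(lib, proteome = NULL,
                          decoy_prefixes = DECOY_PREFIXES_DEFAULT) {
  td <- classify_target_decoy(lib, proteome, decoy_prefixes)
  log <- .empty_change_log()
  drop <- lib$assays$assay_id[td$class == "decoy"]
  mixed <- lib$assays$assay_id[td$class == "mixed"]
  for (id in drop) log <- .log_change(log, id, "removed", "decoy assay")
  for (id in mixed)
    log <- .log_change(log, id, "retained", "mixed target/decoy assay")
  out <- subset_library(lib, setdiff(lib$assays$assay_id, drop))
  attr(out, "change_log") <- log
  out
}

#' Merge redundant precursor occurrences
#'
#' Duplicate occurrences of the same precursor ion (modified sequence x
#' charge) are merged by summing intensities per fragment key (series,
#' ordinal, charge, loss; unlabeled fragments key on m/z rounded to 4
#' decimals), taking the median RT, then keeping the top `n_top` fragments.
#'
#' @param lib A `spectral_library`.
#' @param n_top Fragments kept per merged precursor.
#' @return A consensus-style `spectral_library`.
#' @export
merge_redundant <- function(lib, n_top = 6L) {
  a <- lib$assays
  f <- lib$fragments
  prec_key <- paste(a$modified_sequence, a$precursor_charge, sep = "/")
  groups <- split(seq_len(nrow(a)), prec_key)
  groups <- groups[order(vapply(groups, min, integer(1)))]  # file order
  new_assays <- list()
  new_frags <- list()
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    first <- rows[1]
    ids <- a$assay_id[rows]
    fi <- f[f$assay_id %in% ids, , drop = FALSE]
    fkey <- ifelse(!is.na(fi$series) & fi$series %in% c("b", "y") &
                     !is.na(fi$ordinal),
                   paste(fi$series, fi$ordinal, fi$charge,
                         ifelse(is.na(fi$loss), "", fi$loss)),
                   paste("mz", sprintf("%.4f", fi$mz)))
    agg_idx <- split(seq_len(nrow(fi)), fkey)
    agg_idx <- agg_idx[order(vapply(agg_idx, min, integer(1)))]
    merged <- do.call(rbind, lapply(agg_idx, function(idx) {
      data.frame(assay_id = g,
                 mz = fi$mz[idx[1]],
                 intensity = sum(fi$intensity[idx], na.rm = TRUE),
                 series = fi$series[idx[1]],
                 ordinal = fi$ordinal[idx[1]],
                 charge = fi$charge[idx[1]],
                 loss = fi$loss[idx[1]],
                 stringsAsFactors = FALSE)
    }))
    new_assays[[g]] <- data.frame(
      assay_id = g,
      modified_sequence = a$modified_sequence[first],
      stripped_sequence = a$stripped_sequence[first],
      precursor_charge = a$precursor_charge[first],
      precursor_mz = a$precursor_mz[first],
      rt = stats::median(a$rt[rows]),
      protein_ids = a$protein_ids[first],
      decoy = a$decoy[first],
      group_id = a$group_id[first],
      stringsAsFactors = FALSE)
    new_frags[[g]] <- merged
  }
  out <- spectral_library(do.call(rbind, new_assays),
                          do.call(rbind, new_frags),
                          dialect = lib$dialect,
                          source_columns = lib$source_columns)
  rownames(out$assays) <- NULL
  rownames(out$fragments) <- NULL
  limit_top_n_fragments(out, n_top)
}

#' Shift all retention times by a constant
#'
#' Used e.g. to move iRT scales into positive values before importing a
#' library into DIA software that rejects negative values.
#'
#' @param lib A `spectral_library`.
#' @param offset RT units added to every assay RT.
#' @return A `spectral_library`.
#' @export
shift_rt <- function(lib, offset) {
  lib$assays$rt <- lib$assays$rt + offset
  lib
}

#' Full repair pipeline: mass correction then conflict filtering
#'
#' Mirrors the tandem repair workflow: rewrite fragment m/z to theoretical
#' values, then segregate assays whose fragments fall into their precursor's
#' DIA bin. The clean output is free of mass errors and conflicts.
#'
#' @param lib A `spectral_library`.
#' @param scheme A `swath_scheme`.
#' @param scope Mass-correction scope, see [correct_masses()].
#' @param params [assess_params()].
#' @return A `repair_outcome` with `corrected_library`, `clean_library`,
#'   `problem_library`, `conflicts`, `change_log`.
#' @export
repair_library <- function(lib, scheme, scope = "fragments",
                           params = assess_params()) {
  corrected <- correct_masses(lib, scope = scope, params = params)
  log <- attr(corrected, "change_log")
  fc <- filter_conflicts(corrected, scheme)
  structure(list(corrected_library = corrected,
                 clean_library = fc$clean_library,
                 problem_library = fc$problem_library,
                 conflicts = fc$conflicts,
                 change_log = rbind(log, fc$change_log)),
            class = "repair_outcome")
}
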