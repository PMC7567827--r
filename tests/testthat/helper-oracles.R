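# Independent oracles and small in-code fixtures shared across tests.

# --- elemental-composition mass oracle -------------------------------------
# Monoisotopic masses recomputed from residue elemental compositions with
# independently typed isotope masses; deliberately not the package's table.
.ORACLE_ISO <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
                 O = 15.9949146196, S = 31.97207100)
.ORACLE_COMP <- list( # C, H, N, O, S atom counts per residue
  G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))

oracle_residue_mass <- function(aa) {
  n <- .ORACLE_COMP[[aa]]
  n[1] * .ORACLE_ISO["C"] + n[2] * .ORACLE_ISO["H"] +
    n[3] * .ORACLE_ISO["N"] + n[4] * .ORACLE_ISO["O"] +
    n[5] * .ORACLE_ISO["S"]
}

oracle_neutral_mass <- function(seq, mod_delta = 0) {
  water <- 2 * .ORACLE_ISO["H"] + .ORACLE_ISO["O"]
  unname(sum(vapply(strsplit(seq, "")[[1]], oracle_residue_mass,
                    numeric(1))) + water + mod_delta)
}

random_peptide <- function(len) {
  paste(sample(names(.ORACLE_COMP), len, replace = TRUE), collapse = "")
}

# --- brute-force digestion oracle ------------------------------------------
# Enumerates every substring of the protein and keeps those whose bounds
# fall on cleavage sites (or termini) with at most max_mc internal sites.
oracle_digest <- function(seq, max_mc = 2, len_range = c(1, Inf),
                          suppress_proline = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  is_site <- function(i) {       # cleavage between i and i+1
    i >= 1 && i < n && chars[i] %in% c("K", "R") &&
      !(suppress_proline && chars[i + 1] == "P")
  }
  out <- character(0)
  for (s in 1:n) for (e in s:n) {
    if (!(s == 1 || is_site(s - 1))) next
    if (!(e == n || is_site(e))) next
    internal <- sum(vapply(s:(e - 1), is_site, logical(1)))
    if (e == s) internal <- 0
    len <- e - s + 1
    if (internal <= max_mc && len >= len_range[1] && len <= len_range[2]) {
      out <- c(out, substr(seq, s, e))
    }
  }
  sort(out)
}

# --- brute-force conflict oracle -------------------------------------------
# Exhaustive (assay x window x fragment) scan with half-open windows.
oracle_conflicts <- function(lib, scheme) {
  conflict_ids <- integer(0)
  n_frag <- 0L
  for (i in seq_len(nrow(lib$assays))) {
    pmz <- lib$assays$precursor_mz[i]
    id <- lib$assays$assay_id[i]
    frs <- lib$fragments[lib$fragments$assay_id == id, , drop = FALSE]
    hit <- FALSE
    for (w in seq_len(nrow(scheme))) {
      if (pmz >= scheme$start[w] && pmz < scheme$end[w]) {
        for (j in seq_len(nrow(frs))) {
          if (frs$mz[j] >= scheme$start[w] && frs$mz[j] < scheme$end[w]) {
            hit <- TRUE
          }
        }
      }
    }
    # count distinct conflicting fragments (a fragment may sit in several
    # windows; count it once, as the package does)
    if (nrow(frs) > 0) {
      fc <- vapply(seq_len(nrow(frs)), function(j) {
        any(pmz >= scheme$start & pmz < scheme$end &
              frs$mz[j] >= scheme$start & frs$mz[j] < scheme$end)
      }, logical(1))
      n_frag <- n_frag + sum(fc)
      if (any(fc)) conflict_ids <- c(conflict_ids, id)
    }
  }
  list(conflict_ids = sort(unique(conflict_ids)), n_frag = n_frag)
}

# --- tiny hand-built library -----------------------------------------------
# Two tryptic peptides at 2+ and 3+, six theoretical y/b fragments each.
make_hand_library <- function(peptides = c("ELVISLIVEK", "TENNESSEER"),
                              charges = c(2L, 3L), n_frag = 6L,
                              rt = NULL, proteins = NULL) {
  assays <- list(); frags <- list(); aid <- 0L
  for (p in seq_along(peptides)) {
    pep <- peptides[p]
    n <- nchar(parse_modified_sequence(pep)$stripped_sequence)
    for (z in charges) {
      aid <- aid + 1L
      ords <- rep(seq.int(2L, n - 1L), length.out = n_frag)
      series <- rep(c("y", "b"), length.out = n_frag)
      mz <- vapply(seq_len(n_frag), function(k) {
        fragment_mz(pep, series[k], ords[k], 1L)
      }, numeric(1))
      assays[[aid]] <- data.frame(
        assay_id = aid, modified_sequence = pep, stripped_sequence = pep,
        precursor_charge = z, precursor_mz = precursor_mz(pep, z),
        rt = if (is.null(rt)) 10 * p else rt[p],
        protein_ids = if (is.null(proteins)) sprintf("PROT%02d", p)
                      else proteins[p],
        decoy = NA, group_id = NA_character_, stringsAsFactors = FALSE)
      frags[[aid]] <- data.frame(
        assay_id = aid, mz = mz,
        intensity = seq(1000, by = -100, length.out = n_frag),
        series = series, ordinal = ords, charge = 1L,
        loss = NA_character_, stringsAsFactors = FALSE)
    }
  }
  spectral_library(do.call(rbind, assays), do.call(rbind, frags))
}

# Canonical multiset view of a library for round-trip comparisons: every
# assay/fragment field that defines identity, rounded to the write precision.
library_multiset <- function(lib) {
  a <- lib$assays
  f <- lib$fragments
  idx <- match(f$assay_id, a$assay_id)
  df <- data.frame(
    modseq = a$modified_sequence[idx], z = a$precursor_charge[idx],
    series = f$series, ordinal = f$ordinal, fz = f$charge,
    prot = a$protein_ids[idx], pmz = a$precursor_mz[idx],
    rt = a$rt[idx], fmz = f$mz, int = f$intensity,
    stringsAsFactors = FALSE)
  # order on discrete keys only, so 1e-6-level write/read rounding cannot
  # permute rows; numeric columns are then compared with tolerance
  df <- df[order(df$modseq, df$z, df$series, df$ordinal, df$fz, df$fmz), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
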