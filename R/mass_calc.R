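# Peptide and fragment-ion mass calculus: modified-sequence parsing across
# library dialects, monoisotopic neutral mass, precursor m/z and b/y fragment
# ion m/z, plus nearest-ion annotation for libraries without ion-series
# columns.

#' Residue mass table
#'
#' Returns the monoisotopic residue-mass table used throughout the package,
#' together with the water and proton mass constants.
#'
#' @return A list with elements `residues` (named numeric vector, Da),
#'   `water` and `proton` (Da).
#' @export
residue_mass_table <- function() {
  list(residues = RESIDUE_MASSES, water = WATER_MASS, proton = PROTON_MASS)
}

# Site compatibility for built-in modifications ("*" = any residue).
.mod_sites <- c(
  Carbamidomethyl = "C", Oxidation = "MW", Acetyl = "*", Phospho = "STY",
  Deamidated = "NQ", Methyl = "*", `Gln->pyro-Glu` = "Q"
)

.resolve_mod_token <- function(token) {
  token <- trimws(token)
  reg <- MODIFICATION_REGISTRY
  if (grepl("^unimod:[0-9]+$", tolower(token))) {
    id <- as.integer(sub("^unimod:", "", tolower(token)))
    hit <- match(id, reg$unimod_id)
    if (!is.na(hit)) {
      return(list(name = reg$name[hit], delta = reg$delta_mass[hit], known = TRUE))
    }
    return(list(name = token, delta = NA_real_, known = FALSE))
  }
  if (grepl("^[+-]?[0-9]*\\.?[0-9]+$", token)) {
    d <- as.numeric(token)
    hit <- which(abs(reg$delta_mass - d) <= 0.001)
    if (length(hit) > 0) {
      hit <- hit[which.min(abs(reg$delta_mass[hit] - d))]
      return(list(name = reg$name[hit], delta = reg$delta_mass[hit], known = TRUE))
    }
    # an explicit numeric delta is usable even without a registry name
    return(list(name = sprintf("Delta:%+.4f", d), delta = d, known = TRUE))
  }
  key <- tolower(sub("\\s*\\([A-Za-z*-]*\\)$", "", token))
  for (nm in reg$name) {
    if (key == tolower(nm) || key %in% MODIFICATION_ALIASES[[nm]]) {
      hit <- match(nm, reg$name)
      return(list(name = nm, delta = reg$delta_mass[hit], known = TRUE))
    }
  }
  list(name = token, delta = NA_real_, known = FALSE)
}

#' Parse a modified peptide sequence
#'
#' Understands the modification notations found in OpenSWATH, PeakView and
#' Spectronaut transition lists: UniMod (`"C(UniMod:4)"`), bracketed names
#' (`"C[Carbamidomethyl (C)]"`), bracketed mass deltas (`"C[+57.0214]"`) and
#' PeakView short codes (`"C[CAM]"`). Leading/trailing underscores and dots
#' (Spectronaut / SpectraST decorations) are ignored. A modification group
#' before the first residue is taken as an N-terminal modification.
#'
#' Unknown modification labels and non-standard residues (B, Z, X, ...) do not
#' raise an error: the returned object carries `verifiable = FALSE` and the
#' offending labels, so library-level code can count the assay as
#' unverifiable. Structural problems (unbalanced brackets, a modification on
#' an incompatible residue) are errors.
#'
#' @param text Modified sequence string.
#' @param dialect Optional dialect tag; parsing is notation-driven, so this is
#'   accepted for interface symmetry and unused.
#' @return An object of class `modified_peptide`: a list with
#'   `stripped_sequence`, `mods` (data frame of `position`, `name`, `delta`),
#'   `nterm`/`cterm` (single-row data frames or NULL), `verifiable`,
#'   `unknown_mods`, `nonstandard_residues`.
#' @export
parse_modified_sequence <- function(text, dialect = NULL) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("^_+|_+$", "", text)
  s <- gsub("^\\.+|\\.+$", "", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  residues <- character(0)
  mods <- list()
  nterm <- NULL
  unknown <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("(", "[")) {
      close <- if (ch == "(") ")" else "]"
      j <- i + 1L
      while (j <= n && chars[j] != close) j <- j + 1L
      if (j > n) stop("unbalanced brackets in modified sequence: ", text)
      token <- substr(s, i + 1L, j - 1L)
      res <- .resolve_mod_token(token)
      if (!res$known) unknown <- c(unknown, token)
      pos <- length(residues)
      if (pos == 0L) {
        nterm <- data.frame(name = res$name, delta = res$delta,
                            stringsAsFactors = FALSE)
      } else {
        sites <- .mod_sites[res$name]
        if (!is.na(sites) && sites != "*" &&
            !grepl(residues[pos], sites, fixed = TRUE)) {
          stop(sprintf("modification '%s' not compatible with residue '%s'",
                       res$name, residues[pos]))
        }
        mods[[length(mods) + 1L]] <- data.frame(
          position = pos, name = res$name, delta = res$delta,
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      residues <- c(residues, toupper(ch))
      i <- i + 1L
    } else if (ch %in% c(")", "]")) {
      stop("unbalanced brackets in modified sequence: ", text)
    } else {
      stop("unexpected character '", ch, "' in modified sequence: ", text)
    }
  }
  stripped <- paste(residues, collapse = "")
  if (stripped == "") stop("empty peptide sequence: ", text)
  nonstd <- setdiff(unique(residues), STANDARD_RESIDUES)
  mods_df <- if (length(mods) > 0) do.call(rbind, mods) else
    data.frame(position = integer(0), name = character(0),
               delta = numeric(0), stringsAsFactors = FALSE)
  structure(list(
    stripped_sequence = stripped,
    mods = mods_df,
    nterm = nterm,
    cterm = NULL,
    verifiable = length(unknown) == 0L && length(nonstd) == 0L,
    unknown_mods = unknown,
    nonstandard_residues = nonstd
  ), class = "modified_peptide")
}

# Per-position residue + modification masses; NA entries mark unknown
# residues. N-/C-terminal modification deltas are folded onto the first and
# last positions so ion sums stay simple.
.position_masses <- function(pep, table = residue_mass_table()) {
  m <- unname(table$residues[strsplit(pep$stripped_sequence, "")[[1]]])
  if (nrow(pep$mods) > 0) {
    m[pep$mods$position] <- m[pep$mods$position] + pep$mods$delta
  }
  if (!is.null(pep$nterm)) m[1L] <- m[1L] + pep$nterm$delta
  if (!is.null(pep$cterm)) m[length(m)] <- m[length(m)] + pep$cterm$delta
  m
}

#' Monoisotopic neutral peptide mass
#'
#' Sum of residue masses, water, and all modification deltas. Returns `NA`
#' (the unverifiable-assay signal) rather than erroring when the peptide
#' contains non-standard residues or unresolved modifications.
#'
#' @param pep A `modified_peptide` (or a plain sequence string, parsed on the
#'   fly).
#' @param table Mass table from [residue_mass_table()].
#' @return Neutral monoisotopic mass in Da, or `NA_real_`.
#' @export
peptide_neutral_mass <- function(pep, table = residue_mass_table()) {
  if (is.character(pep)) pep <- parse_modified_sequence(pep)
  pm <- .position_masses(pep, table)
  if (anyNA(pm)) return(NA_real_)
  sum(pm) + table$water
}

#' Theoretical precursor m/z
#'
#' @param pep A `modified_peptide` or sequence string.
#' @param charge Positive precursor charge.
#' @param table Mass table.
#' @return (neutral mass + charge protons) / charge, or `NA_real_` if the
#'   peptide is unverifiable.
#' @export
precursor_mz <- function(pep, charge, table = residue_mass_table()) {
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) || charge < 1)
    stop("charge must be a positive integer")
  m <- peptide_neutral_mass(pep, table)
  (m + charge * table$proton) / charge
}

#' Theoretical fragment-ion m/z (b/y series)
#'
#' @param pep A `modified_peptide` or sequence string.
#' @param series `"b"` or `"y"`.
#' @param ordinal Series index, 1 to length(peptide) - 1.
#' @param charge Positive fragment charge.
#' @param table Mass table.
#' @return m/z in Th, or `NA_real_` for unverifiable peptides.
#' @export
fragment_mz <- function(pep, series, ordinal, charge = 1L,
                        table = residue_mass_table()) {
  if (is.character(pep)) pep <- parse_modified_sequence(pep)
  if (!series %in% c("b", "y")) stop("unsupported ion series: ", series)
  if (charge < 1) stop("charge must be >= 1")
  pm <- .position_masses(pep, table)
  n <- length(pm)
  if (ordinal < 1 || ordinal > n - 1)
    stop("ordinal out of range: ", ordinal, " for peptide of length ", n)
  if (anyNA(pm)) return(NA_real_)
  if (series == "b") {
    (sum(pm[seq_len(ordinal)]) + charge * table$proton) / charge
  } else {
    (sum(pm[seq.int(n - ordinal + 1L, n)]) + table$water +
       charge * table$proton) / charge
  }
}

#' All theoretical b/y ions of a peptide
#'
#' @param pep A `modified_peptide` or sequence string.
#' @param charge_max Highest fragment charge to enumerate.
#' @param table Mass table.
#' @return Data frame with columns `series`, `ordinal`, `charge`, `mz`;
#'   zero rows if the peptide is unverifiable.
#' @export
theoretical_ions <- function(pep, charge_max = 1L,
                             table = residue_mass_table()) {
  if (is.character(pep)) pep <- parse_modified_sequence(pep)
  pm <- .position_masses(pep, table)
  n <- length(pm)
  empty <- data.frame(series = character(0), ordinal = integer(0),
                      charge = integer(0), mz = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2L || anyNA(pm)) return(empty)
  b_neutral <- cumsum(pm)[seq_len(n - 1L)]
  y_neutral <- cumsum(rev(pm))[seq_len(n - 1L)] + table$water
  out <- do.call(rbind, lapply(seq_len(charge_max), function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1L),
      ordinal = rep(seq_len(n - 1L), times = 2L),
      charge = z,
      mz = c((b_neutral + z * table$proton) / z,
             (y_neutral + z * table$proton) / z),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Annotate an observed fragment m/z against theory
#'
#' Finds the nearest theoretical b/y ion within `tol`. Ties are broken by
#' smaller absolute mass difference, then y over b, then lower charge.
#'
#' @param obs_mz Observed fragment m/z.
#' @param pep A `modified_peptide` or sequence string.
#' @param charge_max Highest fragment charge considered.
#' @param tol Match tolerance in Da (must be > 0).
#' @param table Mass table.
#' @return A list `(series, ordinal, charge, mz, delta)` or `NULL` when no
#'   ion lies within tolerance.
#' @export
annotate_fragment <- function(obs_mz, pep, charge_max = 2L, tol = 0.05,
                              table = residue_mass_table()) {
  stopifnot(tol > 0)
  ions <- theoretical_ions(pep, charge_max = charge_max, table = table)
  if (nrow(ions) == 0L) return(NULL)
  ions$delta <- obs_mz - ions$mz
  ions <- ions[abs(ions$delta) <= tol, , drop = FALSE]
  if (nrow(ions) == 0L) return(NULL)
  ord <- order(abs(ions$delta), ions$series != "y", ions$charge)
  best <- ions[ord[1L], ]
  list(series = best$series, ordinal = best$ordinal, charge = best$charge,
       mz = best$mz, delta = best$delta)
}
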