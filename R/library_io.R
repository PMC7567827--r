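# Reading and writing spectral assay libraries in the OpenSWATH, PeakView and
# Spectronaut tab-separated dialects, SWATH definition files, and the
# peptide->protein index built by in-silico digestion of a FASTA proteome.
# Prosit generic text is Spectronaut-compatible and handled by that dialect.

DIALECTS <- c("openswath", "peakview", "spectronaut")

.dialect_fingerprints <- list(
  peakview = c("Q1", "Q3", "prec_z", "frg_type"),
  openswath = c("PrecursorMz", "ProductMz", "transition_group_id"),
  spectronaut = c("PrecursorMz", "FragmentMz", "ModifiedPeptide")
)

#' Detect the dialect of a transition-list file
#'
#' Decides by required-column fingerprint on the header line.
#'
#' @param path Path to a tab-separated library file.
#' @return One of `"openswath"`, `"peakview"`, `"spectronaut"`.
#' @export
detect_dialect <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  for (d in names(.dialect_fingerprints)) {
    if (all(.dialect_fingerprints[[d]] %in% header)) return(d)
  }
  missing <- vapply(names(.dialect_fingerprints), function(d) {
    paste0(d, ": ", paste(setdiff(.dialect_fingerprints[[d]], header),
                          collapse = ", "))
  }, character(1))
  stop("unknown library format; missing fingerprint columns per dialect -> ",
       paste(missing, collapse = " | "))
}

.first_present <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit) == 0L) return(NULL)
  df[[hit[1L]]]
}

# Normalize a protein-id cell to a ';'-joined accession string. OpenSWATH
# exports sometimes prefix with a count, e.g. "2/sp|P1|/sp|P2|".
.normalize_proteins <- function(x) {
  vapply(x, function(p) {
    if (is.na(p) || p == "") return(NA_character_)
    if (grepl("^[0-9]+/", p)) {
      parts <- strsplit(sub("^[0-9]+/", "", p), "/", fixed = TRUE)[[1]]
    } else {
      parts <- strsplit(p, ";", fixed = TRUE)[[1]]
    }
    paste(trimws(parts), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

.parse_decoy_col <- function(x) {
  if (is.null(x)) return(NULL)
  tolower(trimws(x)) %in% c("1", "true", "t", "yes", "decoy")
}

.num <- function(x) suppressWarnings(as.numeric(x))

#' Construct a spectral library object
#'
#' Low-level constructor; most users obtain libraries from [read_library()]
#' or [generate_library()].
#'
#' @param assays Data frame with one row per assay occurrence: `assay_id`,
#'   `modified_sequence`, `stripped_sequence`, `precursor_charge`,
#'   `precursor_mz`, `rt`, `protein_ids` (';'-joined), `decoy` (logical,
#'   may be NA).
#' @param fragments Data frame with `assay_id`, `mz`, `intensity`, `series`
#'   ("b"/"y"/"other"), `ordinal`, `charge`, `loss`.
#' @param dialect Source dialect tag.
#' @param source_columns Raw header preserved for round-trips.
#' @param rejected Data frame of rejected input rows (`row`, `reason`).
#' @param n_input_rows Fragment rows seen in the input file.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(assays, fragments, dialect = "openswath",
                             source_columns = character(0),
                             rejected = NULL, n_input_rows = nrow(fragments)) {
  stopifnot(is.data.frame(assays), is.data.frame(fragments))
  if (is.null(rejected))
    rejected <- data.frame(row = integer(0), reason = character(0),
                           stringsAsFactors = FALSE)
  structure(list(assays = assays, fragments = fragments, dialect = dialect,
                 source_columns = source_columns, rejected = rejected,
                 n_input_rows = n_input_rows),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf(
    "spectral_library [%s]: %d assays, %d fragment rows, %d rejected rows\n",
    x$dialect, nrow(x$assays), nrow(x$fragments), nrow(x$rejected)))
  invisible(x)
}

.normalize_series <- function(x) {
  s <- tolower(substr(trimws(x), 1L, 1L))
  ifelse(s %in% c("b", "y"), s, "other")
}

# Map the raw TSV (all-character) to canonical per-row fields for a dialect.
.canonical_rows <- function(raw, dialect) {
  if (dialect == "openswath") {
    list(
      precursor_mz = raw$PrecursorMz,
      product_mz = raw$ProductMz,
      intensity = raw$LibraryIntensity,
      rt = raw$Tr_recalibrated,
      modified_sequence = raw$FullUniModPeptideName,
      stripped_sequence = raw$PeptideSequence,
      precursor_charge = raw$PrecursorCharge,
      proteins = raw$ProteinName,
      group = raw$transition_group_id,
      frg_type = .first_present(raw, "FragmentType"),
      frg_nr = .first_present(raw, "FragmentSeriesNumber"),
      frg_z = .first_present(raw, c("FragmentCharge", "ProductCharge")),
      decoy = .first_present(raw, "decoy"))
  } else if (dialect == "peakview") {
    list(
      precursor_mz = raw$Q1,
      product_mz = raw$Q3,
      intensity = raw$relative_intensity,
      rt = .first_present(raw, c("iRT", "RT_detected")),
      modified_sequence = raw$modification_sequence,
      stripped_sequence = raw$stripped_sequence,
      precursor_charge = raw$prec_z,
      proteins = .first_present(raw, c("uniprot_id", "protein_name")),
      group = NULL,
      frg_type = raw$frg_type,
      frg_nr = raw$frg_nr,
      frg_z = raw$frg_z,
      decoy = .first_present(raw, "decoy"))
  } else if (dialect == "spectronaut") {
    list(
      precursor_mz = raw$PrecursorMz,
      product_mz = raw$FragmentMz,
      intensity = .first_present(raw, c("RelativeIntensity",
                                        "RelativeFragmentIntensity")),
      rt = .first_present(raw, c("iRT", "RT")),
      modified_sequence = raw$ModifiedPeptide,
      stripped_sequence = raw$StrippedPeptide,
      precursor_charge = raw$PrecursorCharge,
      proteins = .first_present(raw, c("ProteinGroups", "UniprotId")),
      group = NULL,
      frg_type = raw$FragmentType,
      frg_nr = raw$FragmentNumber,
      frg_z = raw$FragmentCharge,
      decoy = .first_present(raw, "decoy"))
  } else {
    stop("unsupported dialect: ", dialect)
  }
}

.required_columns <- list(
  openswath = c("PrecursorMz", "ProductMz", "LibraryIntensity",
                "transition_group_id", "PeptideSequence",
                "FullUniModPeptideName", "PrecursorCharge", "ProteinName",
                "Tr_recalibrated"),
  peakview = c("Q1", "Q3", "stripped_sequence", "modification_sequence",
               "prec_z", "frg_type", "frg_z", "frg_nr", "relative_intensity"),
  spectronaut = c("PrecursorMz", "FragmentMz", "ModifiedPeptide",
                  "StrippedPeptide", "PrecursorCharge", "FragmentType",
                  "FragmentNumber", "FragmentCharge")
)

#' Read a spectral assay library
#'
#' Groups fragment rows under their precursor: in the OpenSWATH dialect by
#' `transition_group_id`, otherwise by contiguous runs of the same
#' (modified sequence, precursor charge), so duplicate occurrences in
#' redundant libraries stay distinct. Rows whose m/z does not parse as a
#' decimal number are collected in the `rejected` slot, never silently
#' dropped.
#'
#' @param path Tab-separated library file.
#' @param dialect Optional dialect tag; auto-detected when NULL.
#' @return A [spectral_library()] object.
#' @export
read_library <- function(path, dialect = NULL) {
  if (is.null(dialect)) dialect <- detect_dialect(path)
  dialect <- match.arg(dialect, DIALECTS)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = c("NA", ""))
  miss <- setdiff(.required_columns[[dialect]], names(raw))
  if (length(miss) > 0)
    stop("missing required ", dialect, " columns: ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) stop("empty library: ", path)
  cr <- .canonical_rows(raw, dialect)
  n <- nrow(raw)

  precursor_mz <- .num(cr$precursor_mz)
  product_mz <- .num(cr$product_mz)
  intensity <- .num(cr$intensity)
  rt <- if (is.null(cr$rt)) rep(NA_real_, n) else .num(cr$rt)
  charge <- suppressWarnings(as.integer(cr$precursor_charge))
  decoy <- .parse_decoy_col(cr$decoy)
  if (is.null(decoy)) decoy <- rep(NA, n)

  bad <- which(is.na(product_mz) | is.na(precursor_mz) | is.na(charge))
  reasons <- vapply(bad, function(i) {
    if (is.na(product_mz[i])) "unparseable fragment m/z"
    else if (is.na(precursor_mz[i])) "unparseable precursor m/z"
    else "unparseable precursor charge"
  }, character(1))
  keep <- setdiff(seq_len(n), bad)
  if (length(keep) == 0L) stop("no parseable transition rows in ", path)

  group_key <- if (!is.null(cr$group)) cr$group[keep] else
    paste(cr$modified_sequence[keep], charge[keep], sep = "/")
  # contiguous runs of the same key are one occurrence; a re-appearance
  # later in the file is a new occurrence (redundant library support)
  r <- rle(group_key)
  occ <- rep(seq_along(r$lengths), r$lengths)

  first <- keep[!duplicated(occ)]
  assays <- data.frame(
    assay_id = seq_along(first),
    modified_sequence = cr$modified_sequence[first],
    stripped_sequence = cr$stripped_sequence[first],
    precursor_charge = charge[first],
    precursor_mz = precursor_mz[first],
    rt = rt[first],
    protein_ids = .normalize_proteins(cr$proteins[first]),
    decoy = decoy[first],
    group_id = if (!is.null(cr$group)) cr$group[first] else NA_character_,
    stringsAsFactors = FALSE)

  frg_type <- if (is.null(cr$frg_type)) rep(NA_character_, n) else cr$frg_type
  frg_nr <- if (is.null(cr$frg_nr)) rep(NA_integer_, n) else
    suppressWarnings(as.integer(cr$frg_nr))
  frg_z <- if (is.null(cr$frg_z)) rep(1L, n) else
    suppressWarnings(as.integer(cr$frg_z))
  fragments <- data.frame(
    assay_id = occ,
    mz = product_mz[keep],
    intensity = intensity[keep],
    series = ifelse(is.na(frg_type[keep]), NA_character_,
                    .normalize_series(frg_type[keep])),
    ordinal = frg_nr[keep],
    charge = ifelse(is.na(frg_z[keep]), 1L, frg_z[keep]),
    loss = NA_character_,
    stringsAsFactors = FALSE)

  rejected <- data.frame(row = bad, reason = reasons,
                         stringsAsFactors = FALSE)
  spectral_library(assays, fragments, dialect = dialect,
                   source_columns = names(raw), rejected = rejected,
                   n_input_rows = n)
}

.fmt_mz <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))

#' Write a spectral library
#'
#' Emits all assays in the target dialect's column order, with m/z printed to
#' six decimal places. The decoy column is written only when any assay
#' carries a dialect decoy flag.
#'
#' @param lib A `spectral_library`.
#' @param path Output path.
#' @param dialect Target dialect (default: the library's own).
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, dialect = lib$dialect) {
  stopifnot(inherits(lib, "spectral_library"))
  dialect <- match.arg(dialect, DIALECTS)
  a <- lib$assays
  f <- lib$fragments
  idx <- match(f$assay_id, a$assay_id)
  group_id <- ifelse(is.na(a$group_id),
                     paste0(a$assay_id, "_", a$modified_sequence, "_",
                            a$precursor_charge),
                     a$group_id)
  series <- ifelse(is.na(f$series), "other", f$series)
  ordinal <- ifelse(is.na(f$ordinal), 0L, f$ordinal)
  has_decoy <- any(!is.na(a$decoy))
  df <- switch(dialect,
    openswath = {
      d <- data.frame(
        PrecursorMz = .fmt_mz(a$precursor_mz[idx]),
        ProductMz = .fmt_mz(f$mz),
        Tr_recalibrated = .fmt_num(a$rt[idx]),
        transition_group_id = group_id[idx],
        PeptideSequence = a$stripped_sequence[idx],
        FullUniModPeptideName = a$modified_sequence[idx],
        PrecursorCharge = a$precursor_charge[idx],
        ProteinName = a$protein_ids[idx],
        LibraryIntensity = .fmt_num(f$intensity),
        FragmentType = series,
        FragmentSeriesNumber = ordinal,
        FragmentCharge = f$charge,
        stringsAsFactors = FALSE, check.names = FALSE)
      if (has_decoy) d$decoy <- as.integer(a$decoy[idx])
      d
    },
    peakview = {
      d <- data.frame(
        Q1 = .fmt_mz(a$precursor_mz[idx]),
        Q3 = .fmt_mz(f$mz),
        RT_detected = .fmt_num(a$rt[idx]),
        protein_name = a$protein_ids[idx],
        uniprot_id = a$protein_ids[idx],
        relative_intensity = .fmt_num(f$intensity),
        stripped_sequence = a$stripped_sequence[idx],
        modification_sequence = a$modified_sequence[idx],
        prec_z = a$precursor_charge[idx],
        frg_type = series,
        frg_z = f$charge,
        frg_nr = ordinal,
        iRT = .fmt_num(a$rt[idx]),
        stringsAsFactors = FALSE, check.names = FALSE)
      if (has_decoy) d$decoy <- as.integer(a$decoy[idx])
      d
    },
    spectronaut = {
      d <- data.frame(
        PrecursorMz = .fmt_mz(a$precursor_mz[idx]),
        FragmentMz = .fmt_mz(f$mz),
        iRT = .fmt_num(a$rt[idx]),
        ModifiedPeptide = a$modified_sequence[idx],
        StrippedPeptide = a$stripped_sequence[idx],
        PrecursorCharge = a$precursor_charge[idx],
        FragmentType = series,
        FragmentNumber = ordinal,
        FragmentCharge = f$charge,
        RelativeIntensity = .fmt_num(f$intensity),
        ProteinGroups = a$protein_ids[idx],
        stringsAsFactors = FALSE, check.names = FALSE)
      if (has_decoy) d$decoy <- as.integer(a$decoy[idx])
      d
    })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a SWATH definition file
#'
#' Expects one isolation window per line: start m/z and end m/z, whitespace-
#' or tab-separated, optional single header line. Windows may overlap (a 1 Th
#' overlap between consecutive windows is the common acquisition design).
#'
#' @param path File path.
#' @return A `swath_scheme` object (data frame with `start`, `end`).
#' @export
read_swath_scheme <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty SWATH definition file: ", path)
  parts <- strsplit(lines, "[\t ]+")
  first <- .num(parts[[1]])
  if (all(is.na(first))) {   # header line (all tokens non-numeric)
    parts <- parts[-1L]
    if (length(parts) == 0L) stop("no window rows in ", path)
  }
  win <- lapply(seq_along(parts), function(i) {
    v <- .num(parts[[i]])
    if (length(v) < 2L || anyNA(v[1:2]))
      stop("non-numeric window line ", i, " in ", path)
    v[1:2]
  })
  m <- do.call(rbind, win)
  swath_scheme(m[, 1], m[, 2])
}

#' Construct a SWATH scheme
#'
#' @param start,end Numeric vectors of window bounds (Th). Windows are
#'   half-open intervals `[start, end)` for membership tests.
#' @return A `swath_scheme` data frame.
#' @export
swath_scheme <- function(start, end) {
  if (any(start >= end))
    stop("invalid window(s): start must be < end")
  structure(data.frame(start = as.numeric(start), end = as.numeric(end)),
            class = c("swath_scheme", "data.frame"))
}

#' Write a SWATH scheme to a definition file
#' @param scheme A `swath_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swath_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme)[, c("start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Build a peptide-to-protein index from a FASTA proteome
#'
#' Digests every protein with the trypsin rule (cleave after K/R, suppressed
#' before P) and indexes peptides within the configured length range and
#' missed-cleavage limit. I and L are treated as distinct residues.
#' Accessions carrying a decoy prefix (`DECOY_`, `decoy_`, `rev_`,
#' `reverse_`) are classed as decoys; `proteome_size` counts target proteins
#' only.
#'
#' @param fasta Path to a protein FASTA file, or a named character vector of
#'   sequences.
#' @param params [digest_params()].
#' @param decoy_prefixes Accession prefixes marking decoy proteins.
#' @return An object of class `proteome_index` with `proteome_size`,
#'   `peptides` (data frame `peptide`, `accession`, `decoy`,
#'   `missed_cleavages`), `peptide_map` (peptide -> accession vector),
#'   `digest_params`.
#' @export
build_proteome_index <- function(fasta, params = digest_params(),
                                 decoy_prefixes = DECOY_PREFIXES_DEFAULT) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    if (length(aa) == 0L) stop("zero proteins in FASTA: ", fasta)
    seqs <- as.character(aa)
    names(seqs) <- vapply(names(aa), function(h) strsplit(h, "\\s+")[[1]][1],
                          character(1), USE.NAMES = FALSE)
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    seqs <- fasta
  } else {
    stop("fasta must be a file path or a named character vector")
  }
  rx <- paste0("^(", paste(decoy_prefixes, collapse = "|"), ")")
  decoy <- grepl(rx, names(seqs))
  pep_list <- lapply(seq_along(seqs), function(i) {
    d <- digest_protein(seqs[[i]], params)
    if (nrow(d) == 0L) return(NULL)
    data.frame(peptide = d$peptide, accession = names(seqs)[i],
               decoy = decoy[i], missed_cleavages = d$missed_cleavages,
               stringsAsFactors = FALSE)
  })
  peptides <- do.call(rbind, pep_list)
  if (is.null(peptides))
    peptides <- data.frame(peptide = character(0), accession = character(0),
                           decoy = logical(0), missed_cleavages = integer(0),
                           stringsAsFactors = FALSE)
  peptides <- unique(peptides[, c("peptide", "accession", "decoy")])
  peptide_map <- split(peptides$accession, peptides$peptide)
  structure(list(
    proteome_size = sum(!decoy),
    n_decoy_proteins = sum(decoy),
    accessions = names(seqs),
    accession_decoy = stats::setNames(decoy, names(seqs)),
    peptides = peptides,
    peptide_map = peptide_map,
    digest_params = params
  ), class = "proteome_index")
}

#' @export
print.proteome_index <- function(x, ...) {
  cat(sprintf(
    "proteome_index: %d target proteins (%d decoy), %d indexed peptides\n",
    x$proteome_size, x$n_decoy_proteins, length(x$peptide_map)))
  invisible(x)
}

# Split a ';'-joined protein_ids field into accessions.
split_protein_ids <- function(x) {
  lapply(x, function(p) {
    if (is.na(p) || p == "") character(0)
    else strsplit(p, ";", fixed = TRUE)[[1]]
  })
}

#' Keep a subset of assays, reindexing assay ids
#'
#' @param lib A `spectral_library`.
#' @param assay_ids Assay ids to keep (order preserved).
#' @return A new `spectral_library`.
#' @export
subset_library <- function(lib, assay_ids) {
  a <- lib$assays[lib$assays$assay_id %in% assay_ids, , drop = FALSE]
  f <- lib$fragments[lib$fragments$assay_id %in% assay_ids, , drop = FALSE]
  new_id <- stats::setNames(seq_len(nrow(a)), a$assay_id)
  f$assay_id <- unname(new_id[as.character(f$assay_id)])
  a$assay_id <- unname(new_id[as.character(a$assay_id)])
  rownames(a) <- NULL
  rownames(f) <- NULL
  spectral_library(a, f, dialect = lib$dialect,
                   source_columns = lib$source_columns,
                   n_input_rows = nrow(f))
}
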