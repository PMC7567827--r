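# In-silico tryptic digestion and missed-cleavage accounting.

#' Digestion parameters
#'
#' @param enzyme Currently only `"trypsin"` (cleave C-terminal to K/R).
#' @param missed_cleavages Maximum internal missed cleavage sites.
#' @param length_range Peptide length range retained by the digest.
#' @param suppress_proline If TRUE (default), K/R followed by P is not cleaved
#'   (the KP/RP rule).
#' @return A `digest_params` list.
#' @export
digest_params <- function(enzyme = "trypsin", missed_cleavages = 2L,
                          length_range = c(7L, 30L),
                          suppress_proline = TRUE) {
  stopifnot(enzyme == "trypsin", missed_cleavages >= 0L,
            length(length_range) == 2L, length_range[1] <= length_range[2])
  structure(list(enzyme = enzyme,
                 missed_cleavages = as.integer(missed_cleavages),
                 length_range = as.integer(length_range),
                 suppress_proline = isTRUE(suppress_proline)),
            class = "digest_params")
}

# Positions i such that trypsin cleaves between residue i and i+1.
.cleavage_sites <- function(seq, suppress_proline = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% c("K", "R"))
  if (suppress_proline) idx <- idx[chars[idx + 1L] != "P"]
  idx
}

#' Tryptic digest of one protein sequence
#'
#' Cleaves C-terminal to K/R (suppressed before P when
#' `params$suppress_proline`), enumerates peptides with up to
#' `params$missed_cleavages` internal missed sites, and filters to the
#' configured length range.
#'
#' @param seq Protein sequence (uppercase residue string).
#' @param params A [digest_params()] object.
#' @return Data frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`.
#' @export
digest_protein <- function(seq, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  n <- nchar(seq)
  sites <- .cleavage_sites(seq, params$suppress_proline)
  bounds <- c(0L, sites, n)          # peptide i spans bounds[i]+1 .. bounds[i+1]
  k <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(k)) {
    for (mc in 0:params$missed_cleavages) {
      j <- i + mc
      if (j > k) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      len <- end - start + 1L
      if (len >= params$length_range[1] && len <= params$length_range[2]) {
        out[[length(out) + 1L]] <- data.frame(
          peptide = substr(seq, start, end), start = start, end = end,
          missed_cleavages = mc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Count internal missed cleavage sites of a peptide
#'
#' An internal K/R (not the C-terminal residue, and not followed by P when
#' the suppression rule is on) counts as one missed cleavage.
#'
#' @param peptides Character vector of peptide sequences.
#' @param suppress_proline Apply the KP/RP suppression rule.
#' @return Integer vector of missed-cleavage counts.
#' @export
count_missed_cleavages <- function(peptides, suppress_proline = TRUE) {
  vapply(peptides, function(p) {
    length(.cleavage_sites(p, suppress_proline))
  }, integer(1), USE.NAMES = FALSE)
}
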