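# Seeded generators for fixture proteomes, SWATH schemes and tryptic
# spectral libraries, plus injectors for the defect classes a QC tool must
# recover: constant fragment m/z offsets, decoy assays, isolation-window
# conflicts and redundant (non-consensus) entries.

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Kyte-Doolittle hydropathy, the RT proxy for simulated iRT values.
.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Simulation configuration
#'
#' Defaults emulate a small consensus tryptic library: ~200 precursor ions
#' (2+ and 3+ of ~100 peptides), theoretical b/y fragment m/z, top-6
#' fragments per precursor, iRT shared across charge states.
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_proteins Proteins in the synthetic proteome.
#' @param protein_length Length range (residues).
#' @param peptides_per_protein Cap on peptides selected per protein.
#' @param charge_states Precursor charges generated per peptide.
#' @param fragments_per_precursor Top-N fragments kept per precursor.
#' @param precursor_mz_range Acquired precursor range (Th); peptide/charge
#'   combinations outside it are not emitted, mirroring libraries built from
#'   data acquired over a fixed precursor window.
#' @param irt_range iRT range the hydrophobicity proxy is mapped into.
#' @param delta_mz,decoy_fraction,conflict_fraction,redundancy_factor
#'   Default defect parameters carried for convenience; the injectors also
#'   accept explicit values.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_proteins = 25L,
                       protein_length = c(150L, 300L),
                       peptides_per_protein = 5L,
                       charge_states = c(2L, 3L),
                       fragments_per_precursor = 6L,
                       precursor_mz_range = c(400, 1250),
                       irt_range = c(-55, 110),
                       delta_mz = 0, decoy_fraction = 0,
                       conflict_fraction = 0, redundancy_factor = 1L) {
  stopifnot(n_proteins >= 1, protein_length[1] <= protein_length[2],
            fragments_per_precursor >= 1,
            decoy_fraction >= 0, decoy_fraction <= 1,
            conflict_fraction >= 0, conflict_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic proteome
#'
#' Random sequences over the 20 standard residues (uniform composition, so
#' K/R sites occur roughly every 10 residues), reproducible under the
#' config seed. Optionally written as FASTA.
#'
#' @param cfg A [sim_config()].
#' @param path Optional FASTA output path.
#' @return A list with `sequences` (named character vector) and `index`
#'   (the [build_proteome_index()] of those sequences).
#' @export
generate_proteome <- function(cfg = sim_config(), path = NULL) {
  seqs <- .with_seed(cfg$seed, {
    lens <- sample(cfg$protein_length[1]:cfg$protein_length[2],
                   cfg$n_proteins, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(STANDARD_RESIDUES, L, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("SYNPROT%04d", seq_along(seqs))
  if (!is.null(path)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  }
  list(sequences = seqs, index = build_proteome_index(seqs))
}

# UniMod-notation modified sequence with fixed carbamidomethyl on C.
.cam_modseq <- function(peptide) {
  gsub("C", "C(UniMod:4)", peptide, fixed = TRUE)
}

#' Generate a synthetic tryptic spectral library
#'
#' Selects tryptic peptides per protein, generates each at the configured
#' charge states with theoretical precursor m/z, and picks the top-N
#' singly-charged b/y fragments by a simulated decreasing-geometric intensity
#' profile. Cysteines carry fixed carbamidomethyl. Each peptide's iRT is a
#' hydrophobicity proxy shared across charge states, so mass-accuracy and
#' cross-charge RT criteria are exactly recoverable (average delta mass 0,
#' RT-fit R-squared 1). When a `scheme` is given, fragments falling into an
#' isolation window containing their precursor are excluded from selection
#' (DIA verification), making the library conflict-free.
#'
#' @param cfg A [sim_config()].
#' @param proteome Result of [generate_proteome()] (or a `proteome_index`
#'   plus sequences list).
#' @param scheme Optional `swath_scheme` for conflict-free selection.
#' @param dialect Dialect tag recorded on the library.
#' @return A `spectral_library`.
#' @export
generate_library <- function(cfg = sim_config(), proteome = NULL,
                             scheme = NULL, dialect = "openswath") {
  if (is.null(proteome)) proteome <- generate_proteome(cfg)
  index <- proteome$index
  peps <- index$peptides[!index$peptides$decoy, , drop = FALSE]
  # deterministic per-protein selection: shortest missed-cleavage form first
  sel <- unlist(lapply(split(peps$peptide, peps$accession), function(p) {
    p <- unique(p)
    p <- p[nchar(p) >= 7 & nchar(p) <= 25]
    utils::head(p, cfg$peptides_per_protein)
  }), use.names = FALSE)
  sel <- unique(sel)
  if (length(sel) == 0L) stop("proteome too small for requested library")

  assays <- list()
  frags <- list()
  .with_seed(cfg$seed + 1L, {
    aid <- 0L
    for (pep_seq in sel) {
      modseq <- .cam_modseq(pep_seq)
      pep <- parse_modified_sequence(modseq)
      gravy <- mean(.KD_SCALE[strsplit(pep_seq, "")[[1]]])
      irt <- cfg$irt_range[1] +
        (gravy + 4.5) / 9 * (cfg$irt_range[2] - cfg$irt_range[1])
      prots <- index$peptide_map[[pep_seq]]
      ladder <- theoretical_ions(pep, charge_max = 1L)
      ladder <- ladder[ladder$ordinal >= 2 & ladder$mz >= 200 &
                         ladder$mz <= 1500, , drop = FALSE]
      for (z in cfg$charge_states) {
        pmz <- precursor_mz(pep, z)
        if (pmz < cfg$precursor_mz_range[1] ||
            pmz > cfg$precursor_mz_range[2]) next
        cand <- ladder
        if (!is.null(scheme)) {
          in_prec <- scheme$start <= pmz & pmz < scheme$end
          if (any(in_prec)) {
            bad <- rep(FALSE, nrow(cand))
            for (w in which(in_prec)) {
              bad <- bad | (cand$mz >= scheme$start[w] &
                              cand$mz < scheme$end[w])
            }
            cand <- cand[!bad, , drop = FALSE]
          }
        }
        if (nrow(cand) < 3L) next
        # geometric intensity profile over a random fragment ordering
        ord <- sample.int(nrow(cand))
        inten <- numeric(nrow(cand))
        inten[ord] <- 10000 * 0.7^(seq_len(nrow(cand)) - 1) *
          stats::runif(nrow(cand), 0.95, 1.05)
        keep <- order(-inten, cand$mz)[
          seq_len(min(cfg$fragments_per_precursor, nrow(cand)))]
        keep <- sort(keep)
        aid <- aid + 1L
        assays[[aid]] <- data.frame(
          assay_id = aid,
          modified_sequence = modseq,
          stripped_sequence = pep_seq,
          precursor_charge = as.integer(z),
          precursor_mz = pmz,
          rt = irt,
          protein_ids = paste(prots, collapse = ";"),
          decoy = NA,
          group_id = NA_character_,
          stringsAsFactors = FALSE)
        frags[[aid]] <- data.frame(
          assay_id = aid,
          mz = cand$mz[keep],
          intensity = round(inten[keep], 4),
          series = cand$series[keep],
          ordinal = cand$ordinal[keep],
          charge = cand$charge[keep],
          loss = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  })
  if (length(assays) == 0L) stop("no assays generated; enlarge the proteome")
  spectral_library(do.call(rbind, assays), do.call(rbind, frags),
                   dialect = dialect)
}

#' Add a constant offset to every fragment m/z
#'
#' Emulates libraries built from observed rather than theoretical fragment
#' masses; precursors are untouched.
#'
#' @param lib A `spectral_library`.
#' @param delta Offset in Da.
#' @return A `spectral_library`.
#' @export
perturb_fragment_mz <- function(lib, delta) {
  lib$fragments$mz <- lib$fragments$mz + delta
  lib
}

#' Inject decoy assays
#'
#' Appends `round(fraction * n_assays)` decoy assays built by shuffling the
#' internal residues of sampled target peptides (the tryptic C-terminal
#' residue stays in place), redrawing until the shuffled sequence is absent
#' from the proteome index. Precursor and fragment m/z are theoretical for
#' the shuffled sequence; protein ids are prefixed `DECOY_`.
#'
#' @param lib A `spectral_library`.
#' @param fraction Decoy fraction of the current assay count, in [0, 1].
#' @param proteome Result of [generate_proteome()] or a `proteome_index`.
#' @param seed Seed for sampling and shuffling.
#' @return A `spectral_library` with decoys appended.
#' @export
inject_decoys <- function(lib, fraction, proteome, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  index <- if (inherits(proteome, "proteome_index")) proteome else
    proteome$index
  n_new <- round(fraction * nrow(lib$assays))
  if (n_new == 0L) return(lib)
  a <- lib$assays
  f <- lib$fragments
  .with_seed(seed, {
    src <- sample(a$assay_id, n_new)
    next_id <- max(a$assay_id)
    for (sid in src) {
      row <- a[a$assay_id == sid, ]
      pep_seq <- row$stripped_sequence
      n <- nchar(pep_seq)
      chars <- strsplit(pep_seq, "")[[1]]
      shuffled <- pep_seq
      for (try in 1:200) {
        cand <- paste(c(sample(chars[-n]), chars[n]), collapse = "")
        if (cand != pep_seq && is.null(index$peptide_map[[cand]])) {
          shuffled <- cand
          break
        }
      }
      modseq <- .cam_modseq(shuffled)
      pep <- parse_modified_sequence(modseq)
      next_id <- next_id + 1L
      fr <- f[f$assay_id == sid, , drop = FALSE]
      fr$assay_id <- next_id
      for (j in seq_len(nrow(fr))) {
        if (!is.na(fr$series[j]) && fr$series[j] %in% c("b", "y") &&
            !is.na(fr$ordinal[j]) && fr$ordinal[j] <= n - 1) {
          fr$mz[j] <- fragment_mz(pep, fr$series[j], fr$ordinal[j],
                                  fr$charge[j])
        }
      }
      prots <- strsplit(row$protein_ids, ";", fixed = TRUE)[[1]]
      a <- rbind(a, data.frame(
        assay_id = next_id,
        modified_sequence = modseq,
        stripped_sequence = shuffled,
        precursor_charge = row$precursor_charge,
        precursor_mz = precursor_mz(pep, row$precursor_charge),
        rt = row$rt,
        protein_ids = paste(paste0("DECOY_", prots), collapse = ";"),
        decoy = NA,
        group_id = NA_character_,
        stringsAsFactors = FALSE))
      f <- rbind(f, fr)
    }
  })
  spectral_library(a, f, dialect = lib$dialect,
                   source_columns = lib$source_columns)
}

#' Inject DIA isolation-window conflicts
#'
#' For a seeded sample of currently conflict-free assays whose precursor
#' lies in at least one window, rewrites the m/z of the assay's
#' lowest-intensity fragment to a value inside a window containing the
#' precursor. [detect_conflicts()] then finds exactly those assays.
#'
#' @param lib A `spectral_library`.
#' @param scheme A `swath_scheme`.
#' @param fraction Fraction of assays to perturb, in [0, 1].
#' @param seed Seed for sampling.
#' @return A `spectral_library` with attribute `conflict_assay_ids`.
#' @export
inject_conflicts <- function(lib, scheme, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  k <- round(fraction * nrow(lib$assays))
  if (k == 0L) return(lib)
  cf0 <- detect_conflicts(lib, scheme)
  eligible <- setdiff(
    setdiff(lib$assays$assay_id, cf0$conflict_assay_ids),
    cf0$unverifiable_assay_ids)
  if (length(eligible) < k)
    stop("only ", length(eligible), " assays eligible for conflict injection")
  f <- lib$fragments
  chosen <- .with_seed(seed, sample(eligible, k))
  u <- .with_seed(seed + 1L, stats::runif(k, 0.05, 0.95))
  for (i in seq_along(chosen)) {
    id <- chosen[i]
    pmz <- lib$assays$precursor_mz[lib$assays$assay_id == id]
    w <- which(scheme$start <= pmz & pmz < scheme$end)[1]
    target_mz <- scheme$start[w] + u[i] * (scheme$end[w] - scheme$start[w])
    idx <- which(f$assay_id == id)
    j <- idx[which.min(f$intensity[idx])]
    f$mz[j] <- target_mz
  }
  out <- spectral_library(lib$assays, f, dialect = lib$dialect,
                          source_columns = lib$source_columns)
  attr(out, "conflict_assay_ids") <- sort(chosen)
  out
}

#' Duplicate precursor occurrences (redundant library)
#'
#' Each assay is duplicated `factor` times with multiplicative intensity
#' jitter on the copies (disabled at `factor = 1`), emulating a library
#' built from redundant rather than consensus spectra.
#'
#' @param lib A `spectral_library`.
#' @param factor Occurrences per precursor (>= 1).
#' @param jitter Relative intensity jitter SD for the copies.
#' @param seed Seed for the jitter.
#' @return A `spectral_library`.
#' @export
make_redundant <- function(lib, factor, jitter = 0.05, seed = 1L) {
  stopifnot(factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(lib)
  a <- lib$assays
  f <- lib$fragments
  new_a <- list(); new_f <- list()
  # whole-library copies are appended one after another, so duplicate
  # occurrences of a precursor are non-contiguous in the emitted file (as in
  # replicate-derived raw libraries) and stay distinct on re-read
  .with_seed(seed, {
    nid <- 0L
    for (r in seq_len(factor)) {
      for (i in seq_len(nrow(a))) {
        fi <- f[f$assay_id == a$assay_id[i], , drop = FALSE]
        nid <- nid + 1L
        ar <- a[i, , drop = FALSE]
        ar$assay_id <- nid
        fr <- fi
        fr$assay_id <- nid
        if (r > 1L) {
          fr$intensity <- fr$intensity *
            pmax(0.05, 1 + stats::rnorm(nrow(fr), 0, jitter))
        }
        new_a[[nid]] <- ar
        new_f[[nid]] <- fr
      }
    }
  })
  out_a <- do.call(rbind, new_a)
  rownames(out_a) <- NULL
  spectral_library(out_a, do.call(rbind, new_f), dialect = lib$dialect,
                   source_columns = lib$source_columns)
}

#' Generate a SWATH isolation-window scheme
#'
#' Contiguous coverage of `[mz_start, mz_end]` by `n_windows` windows, each
#' consecutive pair overlapping by exactly `overlap` Th. With
#' `variable = TRUE` window widths are drawn deterministically from the seed
#' (emulating variable-window acquisition); otherwise widths are equal.
#'
#' @param n_windows Number of windows (>= 1).
#' @param mz_start,mz_end Covered precursor range (Th).
#' @param overlap Overlap between consecutive windows (Th).
#' @param variable Draw variable widths.
#' @param seed Seed for the width draw.
#' @return A `swath_scheme`.
#' @export
generate_swath_scheme <- function(n_windows = 100L, mz_start = 400,
                                  mz_end = 1250, overlap = 1,
                                  variable = TRUE, seed = 1L) {
  stopifnot(n_windows >= 1, mz_start < mz_end, overlap >= 0)
  total <- (mz_end - mz_start) + (n_windows - 1) * overlap
  base <- total / n_windows
  if (base <= overlap)
    stop("infeasible: windows would be narrower than the overlap")
  w <- if (variable && n_windows > 1) {
    raw <- .with_seed(seed, stats::runif(n_windows, 0.6, 1.4))
    raw * total / sum(raw)
  } else {
    rep(base, n_windows)
  }
  if (any(w <= overlap))
    stop("infeasible: drawn window width below the overlap")
  start <- numeric(n_windows)
  end <- numeric(n_windows)
  start[1] <- mz_start
  for (i in seq_len(n_windows)) {
    end[i] <- start[i] + w[i]
    if (i < n_windows) start[i + 1] <- end[i] - overlap
  }
  end[n_windows] <- mz_end
  swath_scheme(start, end)
}
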