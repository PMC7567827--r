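---
title: "Assessing and repairing DIA/SWATH spectral libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and repairing DIA/SWATH spectral libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speclibqc)
```

## The problem

DIA/SWATH analysis extracts fragment-ion chromatograms from multiplexed
MS/MS spectra using a spectral assay library: for each precursor ion
(modified peptide and charge state) the library stores the precursor m/z,
a normalized retention time (iRT), and a handful of fragment ions with
their m/z and relative intensities. Because libraries are assembled by long
DDA pipelines (search, statistical validation, consensus building, format
conversion), they accumulate defects that the downstream DIA software will
not complain about but that silently cost identifications or distort
quantities: fragment m/z recorded from observed peaks rather than theory,
decoy assays left over from the search, redundant non-consensus entries,
and fragment ions whose m/z falls inside the isolation window of their own
precursor, where residual un-fragmented precursor signal contaminates the
extracted intensity.

`speclibqc` evaluates a library against a fixed registry of 62 criteria in
five categories (complexity, characteristics, modifications, completeness,
correctness) and can repair two defect classes: mass errors (by rewriting
m/z to theoretical values) and isolation-window conflicts (by segregating
the affected assays).

## The mass model

All masses are monoisotopic. The residue table is derived from elemental
compositions (H = 1.00782503207, C = 12, N = 14.0030740048,
O = 15.9949146196, S = 31.972071 Da), with water 18.0105646837 Da and the
proton 1.00727646688 Da, so sums over peptides are accurate to well below
1e-6 Da. A peptide's neutral mass is the residue sum plus water plus all
modification deltas; the precursor m/z at charge $z$ is
$(M + z\,m_p)/z$; the b/y fragment ions are

$$ b_k = \frac{\sum_{i \le k} m_i + z\,m_p}{z}, \qquad
   y_k = \frac{\sum_{i > n-k} m_i + m_{H_2O} + z\,m_p}{z}. $$

Only the b and y series are generated for theoretical comparison: they
dominate CID/HCD-type fragmentation and are what transition lists carry in
practice. Fragments that match no b/y ion (within the annotation tolerance)
are scored as "other" in the series composition and excluded from
delta-mass averaging rather than guessed at. a/c/x/z ions and neutral-loss
fragments are not validated against theory; a library relying on them will
show a large "other" fraction, which is itself diagnostic.

Modification notations from all supported dialects normalize to one
internal form, resolved by name/alias first and by delta-mass match within
0.001 Da second (so `C[CAM]`, `C(UniMod:4)` and `C[+57.0214]` are the same
type). Unknown modification labels and non-standard residues (B, Z, X) do
not abort the run: the assay becomes *unverifiable* and is counted in the
problem-assay criterion, which mirrors how a QC tool must behave on
real-world exports.

## The criteria registry

The registry is fixed at 62 criteria: 6 complexity, 28 characteristics,
6 modifications, 8 completeness, 14 correctness. Every assessment emits all
62 rows; a criterion whose optional input is missing (no SWATH scheme, no
proteome FASTA, fewer than three 2+/3+ RT pairs) is reported with status
`not_evaluated`, never dropped, so reports from different runs always align
row-for-row.

Design choices worth knowing:

* **Signed average delta mass.** The average of (library − theoretical)
  m/z is signed, not absolute, so a constant injected offset is recovered
  as itself; symmetric random noise averages toward zero while still
  raising the error counts. The flagging tolerance for counting an ion as
  erroneous is 0.01 Da by default and configurable
  (`assess_params(tol_fragment =, tol_precursor =)`); note that an offset
  exactly at the tolerance is not flagged (the comparison is strict).
* **Problem assays** are the disjoint union of assays with at least one
  above-tolerance mass error and unverifiable assays (unparseable
  sequence, or precursor outside every isolation window when a scheme is
  supplied). Each assay is counted once.
* **Half-open windows.** Isolation windows are `[start, end)`. Acquisition
  schemes use overlapping windows (commonly 1 Th), so a closed convention
  would double-assign boundary values; half-open intervals make membership
  unambiguous, and a fragment exactly at a window end is outside it.
* **Conflict rule.** A fragment conflicts if its m/z lies in *any* window
  containing its own precursor — with overlapping windows a precursor can
  sit in two windows and both are checked.
* **RT fit.** Peptides are paired by modified sequence (not stripped), so
  positional modifications do not alias; duplicate occurrences resolve to
  the first, making the fit deterministic. R² is reported from the
  ordinary least-squares fit of RT(3+) on RT(2+).
* **Target/decoy cascade.** An assay is classed by the dialect's decoy
  column when present, else by accession prefixes
  (`DECOY_`, `decoy_`, `rev_`, `reverse_`, configurable), else by the
  proteome index's accession classes; mapping to both target and decoy
  proteins makes it "mixed".
* **Digestion.** Trypsin cleaves C-terminal to K/R except before P
  (toggleable); I and L are distinct residues in peptide-to-protein
  mapping, since transition lists record explicit sequences.

## Repair semantics

`correct_masses()` rewrites fragment m/z (optionally precursor m/z; the
default corrects fragments only, which is the defect observed in practice)
to theoretical values. Labeled fragments are recomputed directly; unlabeled
ones are first annotated against the theoretical ladder (nearest ion within
0.1 Da; ties by smaller deviation, then y over b, then lower charge).
Fragments matching nothing, and whole assays that are unverifiable, pass
through unchanged and are logged. The operation is idempotent.

`filter_conflicts()` moves each assay with at least one conflict fragment
*whole* into the problem library — an assay that needed one of its top
fragments removed is worth inspecting, and the problem library is exactly
the set of conflict assays. A `drop_fragments` mode removes only the
offending fragments instead. Counts are conserved: clean + problem = input.

The tandem pipeline (`repair_library()`: correct, then filter) can create
conflicts where none were visible before — a fragment whose corrected m/z
moves into its precursor's window — which is precisely why the filter runs
second. The clean output re-assesses with zero average delta mass, zero
conflicts and zero problem assays.

Auxiliary operations: `limit_top_n_fragments()` (intensity rank, ties to
the lower m/z), `remove_decoys()` (mixed assays are retained and logged),
`merge_redundant()` (sums intensities per fragment key
(series, ordinal, charge, loss), median RT, then top-N), and `shift_rt()`
for moving negative iRT scales into positive values before import into
tools that reject them.

## What the synthetic generator emulates — and what it does not

The generator exists so that every criterion has a library whose ground
truth is known by construction. `generate_proteome()` draws random
sequences uniformly over the 20 residues (K/R sites therefore appear about
every 10 residues, giving tryptic-length peptides). `generate_library()`
selects tryptic peptides per protein, emits them at 2+ and 3+ with
theoretical precursor m/z restricted to the acquired range (400–1250 Th by
default, matching the common SWATH precursor range — real libraries cannot
contain precursors outside the acquisition window), assigns each peptide a
single iRT from a Kyte–Doolittle hydropathy proxy mapped into [−55, 110]
(only the cross-charge equality matters for the RT-fit criterion), fixes
carbamidomethyl on every cysteine, and keeps the top 6 singly charged b/y
fragments of a decreasing geometric intensity profile
($I_r \propto 0.7^{r-1}$ with ±5% jitter — the jitter makes top-N
selection and tie-breaking exercisable; no claim about real fragment
intensities is intended). When an acquisition scheme is supplied, fragments
falling into a window containing their precursor are excluded from
selection (DIA verification), so the output is conflict-free by
construction.

Default study conditions: 25 proteins × up to 5 peptides × 2 charges ≈ 200
precursor ions with 6 fragments each. The defect injectors reproduce the
defect classes a QC tool must recover: `perturb_fragment_mz()` adds a
constant offset (0.01/0.02/0.05 Da are the canonical magnitudes for
observed-vs-theoretical q3 errors), `inject_decoys()` appends
shuffled-sequence assays absent from the proteome with `DECOY_`-prefixed
accessions (0.001 is the canonical leftover fraction), `inject_conflicts()`
rewrites one fragment per chosen assay to a value inside a window
containing its precursor, and `make_redundant()` replicates occurrences
with intensity jitter (a factor of 7 reproduces the fragments-per-precursor
inflation typical of raw, non-consensus libraries).

Passing tests on these libraries show that each criterion recovers its
injected defect exactly and that the repair operations reach their fixed
points. They do *not* show robustness to everything real data brings:
correlated mass errors, chimeric or mis-assigned spectra, retention-time
nonlinearity between charge states, unusual modifications, or vendor
column variants beyond the three supported dialects.

## Numerical and interface notes

* Problem sizes in the test suite are kept small by design: ~200-precursor
  libraries for perturbation recovery, a 1,000-assay library for the
  exhaustive conflict cross-check, 2,000–10,000 assays for decoy
  accounting; all generators are pure functions of their seed.
* m/z values are written with six decimal places; read–write–read is the
  identity on the assay/fragment multiset in all three dialects.
* Decimal parsing uses the `.` radix only; no locale handling.
* Rows whose m/z does not parse are collected in the library's `rejected`
  slot (input rows = stored + rejected), never silently dropped.
* Occurrence grouping uses `transition_group_id` in the OpenSWATH dialect
  and contiguous runs of (modified sequence, charge) otherwise; duplicate
  precursor occurrences are preserved on read and merged only by the
  explicit `merge_redundant()` operation, so redundancy stays observable.
* Prosit generic text exports are Spectronaut-compatible and are handled by
  the `spectronaut` dialect.

## Known limitations

Only b/y ions are validated; neutral-loss and higher-series fragments are
"other". Conflict detection uses monoisotopic precursor m/z only — the
precursor's isotope envelope (M+1, M+2) can reach into neighbouring
windows, so a fragment just outside the monoisotopic window may still be
contaminated in practice. The exact vendor column sets vary across export
versions; the dialect fingerprints cover the common cores, and unknown
formats fail with an explicit list of missing columns rather than a guess.
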