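# speclibqc

Quality assessment and repair of spectral assay libraries for
data-independent acquisition (DIA/SWATH) proteomics.

Targeted extraction from DIA data stands or falls with the spectral library:
a table of precursor ions (modified peptide + charge, *q1* m/z, normalized
retention time) and their best fragment ions (*q3* m/z, relative intensity).
Libraries assembled by multi-step DDA pipelines routinely carry silent
defects — fragment m/z stored as observed rather than theoretical values,
leftover decoy assays, redundant non-consensus entries, and fragment ions
that fall into the same DIA isolation window as their own precursor, where
residual un-fragmented precursor signal inflates the extracted intensity.
`speclibqc` makes these defects visible before they degrade identification
and quantitation, and can repair them.

## What it computes

Given a transition-list library (OpenSWATH, PeakView or Spectronaut
tab-separated dialect), an optional SWATH definition file (isolation
windows) and an optional proteome FASTA, the assessment evaluates **62
criteria in five categories**:

* **complexity** — peptides, modified peptides, precursor ions, fragment
  ions, proteins;
* **characteristics** — precursor charge distribution, m/z and RT coverage,
  peptide length, missed cleavages (trypsin rule: cleave after K/R, not
  before P), tryptic C-termini, fragments per precursor, b/y ion-series and
  fragment-charge composition, intensity distribution;
* **modifications** — number and types of posttranslational modifications,
  normalized across notation dialects (`C[CAM]`, `C(UniMod:4)`,
  `C[Carbamidomethyl (C)]`, `C[+57.0214]` are one type);
* **completeness** — proteome coverage and proteotypic vs shared peptides
  against an in-silico tryptic digest of the target proteome;
* **correctness** — the diagnostics that matter most for DIA analysis:
  target/decoy/mixed assay percentages; signed average precursor and
  fragment delta mass against theoretical monoisotopic values, where for a
  fragment ion of series b/y with ordinal *k* and charge *z*

  ```
  b_k: ( sum_{i<=k} m_i            + z * m_proton ) / z
  y_k: ( sum_{i>n-k} m_i + m_H2O   + z * m_proton ) / z
  ```

  with per-residue monoisotopic masses `m_i` including modification deltas;
  the cross-charge RT fit (ordinary least squares of RT at 3+ on RT at 2+
  over peptides seen at both charges, R² ≈ 1 in a sound library); and DIA
  verification — precursors with fragment ions inside an isolation window
  `[start, end)` that also contains the precursor.

The repair mode rewrites fragment (optionally precursor) m/z to theoretical
values and segregates conflict assays, producing a mass-corrected library, a
clean library and a problem library, with a line-oriented log of every edit.

A seeded synthetic-library generator (`sim_config()`, `generate_proteome()`,
`generate_library()`, plus injectors for constant m/z offsets, decoys,
window conflicts and redundancy) reproduces each defect class on demand, so
the whole assessment/repair surface is testable without external data.

## Worked example

```r
library(speclibqc)

cfg      <- sim_config(seed = 1)                      # ~200 precursor ions
scheme   <- generate_swath_scheme(n_windows = 100, mz_start = 400,
                                  mz_end = 1250, overlap = 1, seed = 1)
proteome <- generate_proteome(cfg)
lib      <- generate_library(cfg, proteome, scheme = scheme)

bad    <- perturb_fragment_mz(lib, 0.02)              # q3 stored "observed"
report <- assess(bad, scheme = scheme, proteome = proteome$index)

criterion_value(report, "avg_fragment_delta_mass")    # 0.020000 Da
criterion_value(report, "n_mass_error_assays")        # 202
criterion_value(report, "n_problem_assays")           # 202
criterion_value(report, "pct_proteome_coverage")      # 100.0 %
criterion_value(report, "rt_fit_r_squared")           # 1.0000

out <- repair_library(bad, scheme)                    # correct, then filter
clean_report <- assess(out$clean_library, scheme = scheme)
criterion_value(clean_report, "avg_fragment_delta_mass")  # 0.000000 Da
criterion_value(clean_report, "n_conflict_precursors")    # 0
criterion_value(clean_report, "n_problem_assays")         # 0
```

The first report shows every assay flagged: all 1212 fragment ions sit
0.02 Da above theory, so the signed average delta mass recovers the offset
exactly and each of the 202 assays counts as a problem assay. After the
tandem repair (mass correction, then conflict filtering) the clean library
re-assesses error-free.

From a shell, the same workflow runs as:

```sh
speclibqc --library q3bad.tsv --swath windows.txt \
          --mass-correct --filter-conflicts --plots --out qc/
```

writing `assessment_report.tsv` (62 rows), `q3bad_mz_corrected.tsv`,
`q3bad_clean.tsv`, `q3bad_problem.tsv`, `repair_log.tsv` and summary plots.
(The script installs under `exec/`; locate it with
`system.file("exec", "speclibqc", package = "speclibqc")`.)

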