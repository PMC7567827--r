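Package: speclibqc
Title: Quality Assessment and Repair of DIA/SWATH Spectral Assay Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic quality control of spectral assay libraries used in
    data-independent acquisition (DIA/SWATH) proteomics. Reads transition-list
    libraries in the OpenSWATH, PeakView and Spectronaut tab-separated dialects,
    evaluates 62 compliance criteria in five categories (complexity,
    characteristics, modifications, completeness, correctness), including
    precursor/fragment mass accuracy against theoretical monoisotopic b/y ion
    m/z, retention-time cross-charge correlation, target/decoy accounting and
    detection of fragment ions that fall into the DIA isolation window of their
    own precursor. A repair mode rewrites library m/z to theoretical values and
    segregates conflict assays into problem and clean libraries. A seeded
    synthetic-library generator with configurable defect injectors supports
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
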