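Package: iontrees
Title: Spectral Trees from Multi-Stage Mass Spectrometry for Metabolite Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct MS2/MS3 spectral trees from multi-stage electrospray
    mass-spectrometry scans, compare sparse fragmentation spectra with the
    distMS2 quasi-metric, and curate quality-controlled trees in a relational
    (SQLite) spectral-tree library to aid metabolite annotation on direct
    infusion, LC low-resolution and LC high-resolution platforms. Includes
    readers for mzML/mzXML and a plain-text scan-table format, consensus
    (representative) spectrum computation with tolerance binning, ppm-accurate
    fragment annotation from elemental formulas, neutral-loss series detection,
    retention-time utilities for LC-MS2 data, multidimensional scaling of
    spectral distance matrices, and a deterministic synthetic-scan generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    DBI,
    RSQLite,
    mzR
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse
Config/testthat/edition: 3
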