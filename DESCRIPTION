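Package: nhejscan
Title: Repair-Junction Analysis for GFP-Based NHEJ Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing double-strand-break repair junctions from
    two-cut GFP reporter constructs. Infers deletion, insertion and
    microhomology signatures of non-homologous end joining (NHEJ) repair
    products against a post-cut reference, classifies canonical NHEJ versus
    microhomology-mediated end joining (MMEJ), computes an exhaustive
    random-joining null distribution of apparent microhomology, aggregates
    cohort statistics (deletion/insertion spectra, MMEJ fractions, pooled
    two-proportion and pooled t tests), and derives NHEJ efficiency from
    flow-cytometry count tables. Includes a synthetic-data generator with
    full ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
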