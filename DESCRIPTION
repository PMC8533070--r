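Package: amylofam
Title: Conservation of Amyloidogenic Regions Across Protein Ortholog
    Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether the ability of a protein to form
    amyloid is conserved across an ortholog family. Per-residue beta-arch
    and intrinsic-disorder score tracks (read from external predictors or
    produced by bundled simplified stand-in scorers) are turned into
    amyloidogenic region calls, ortholog sets are curated (species
    deduplication, C-terminal fragment and length-outlier removal), calls
    are projected gap-aware onto a multiple alignment, and a per-column
    conservation-of-amyloidogenicity profile is computed and segmented
    into conserved amyloidogenic regions, which can be contrasted with
    plain sequence identity. A synthetic ortholog-family generator with
    implanted motifs and full ground truth makes every stage testable
    without external databases or predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
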