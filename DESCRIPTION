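Package: cypome
Title: Genome-Wide Cytochrome P450 Complement Curation and Comparative
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curation and comparative analysis of fungal cytochrome P450
    complements (CYPomes). Candidate proteins are triaged into P450s,
    fragments, false positives and non-hits by scanning for the EXXR and
    heme-binding CXG signature motifs; curated P450s are assigned families
    and subfamilies against a named reference set using the International
    P450 Nomenclature percent-identity thresholds (>40% family, >55%
    subfamily), with a neighbor-joining phylogeny used to resolve
    borderline subfamily calls. Downstream tools build species-by-family
    presence/absence conservation matrices with hierarchical clustering,
    saprotroph/ectomycorrhizal family partitions, secondary-metabolite
    biosynthetic gene cluster cross-references, and summary statistics.
    A seeded synthetic-proteome generator with planted families, identity
    bands, fragments and decoys makes every pipeline stage testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
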