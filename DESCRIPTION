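Package: phoscycle
Title: Marine Phosphonate-Cycling Gene Survey Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for surveying phosphonate biosynthesis and catabolism
    genes in marine metagenomes. Curates enzyme-family protein reference
    databases by conserved-residue rules and synteny, dereplicates them by
    greedy identity clustering, screens tabular translated-search hits with
    per-gene identity and alignment-length thresholds, normalizes counts by
    gene copy number and length against a five-gene single-copy marker
    baseline to obtain community relative abundances, and provides the
    accompanying statistical layer (genome co-occurrence fractions,
    Shannon diversity and evenness, one-way ANOVA with Tukey HSD, log-log
    phosphate regression, Bray-Curtis distances, ANOSIM). A synthetic-data
    generator produces reference databases, communities, and hit tables
    with known ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    vegan,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
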