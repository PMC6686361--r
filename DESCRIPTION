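Package: mitochar
Title: Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize annotated circular mitochondrial genomes,
    built around the architecture of raptor mitogenomes such as that of the
    Himalayan griffon (Gyps himalayensis, GenBank KY594709): gene-table
    construction with circular coordinate arithmetic (lengths, signed
    intergenic gaps and overlaps, start/stop codon classification including
    incomplete stops), base-composition and AT/GC-skew statistics per gene and
    per codon position, relative synonymous codon usage (RSCU) under the
    vertebrate mitochondrial code, control-region motif scanning and domain
    partitioning, tandem-repeat decomposition of pseudo-control regions, and
    alignment site classification (constant, variable, parsimony-informative).
    A seeded synthetic-mitogenome generator with full ground truth supports
    validation of every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
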