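Package: mitochar
Title: Characterization of Annotated Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing annotated circular insect mitochondrial
    genomes: annotation summary tables (gene sizes, intergenic spacers,
    start/stop codon classification including incomplete stops), nucleotide
    composition and AT/GC skew statistics per region class, codon usage and
    relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial genetic code, circular signed gene-order comparison with
    breakpoint distances and single-gene translocation detection, and
    A+T-rich (control) region feature scanning (ATAGA + poly-T motif, exact
    tandem repeats). Includes a synthetic-genome generator with planted,
    recorded ground truth so the whole pipeline is testable offline, and
    ships the published annotation, composition and codon-usage tables for
    the hawkmoth Ampelophaga rubiginosa (GenBank KT153024) and the mulberry
    white caterpillar moth Rondotia menciana (GenBank KT258908).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
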