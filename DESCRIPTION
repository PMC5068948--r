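Package: divscreen
Title: Candidate-Gene Discovery from Two-Species Transcriptome Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens transcriptome variant data from two closely related
    species for candidate genes involved in species differentiation.
    Implements isoform-to-unigene reduction, SNP filtering and
    species-sharing classification, the interspecific differentiation
    indices D and D-bar, Nei genetic identity and distance over SNP sets,
    six-frame ORF prediction, codon-usage statistics including Wright's
    effective number of codons, reciprocal-best-hit orthology with
    codon-aware alignment, Nei-Gojobori (NG86) Ka/Ks estimation with
    Jukes-Cantor correction, and a branch-specific Ka/Ks candidate rule
    using an outgroup. Ships a synthetic-data generator that plants SNP
    classes and evolves ortholog coding sequences under controlled
    selection pressure, with ground-truth tables for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
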