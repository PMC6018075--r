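Package: gliadinCensus
Title: Classification, Epitope Census and Quantification of Wheat Gliadins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based characterization of wheat gliadin protein sequences:
    signal-peptide maturation by N-terminal signatures, classification into
    the alpha-, gamma- and omega-gliadin families and the omega-1,2/omega-5
    subtypes, domain segmentation, cysteine census with glutenin
    chain-terminator flagging, exhaustive overlapping scans for celiac
    disease (CD) and wheat-dependent exercise-induced anaphylaxis (WDEIA)
    epitopes including the protease-resistant 33-mer, genome-of-origin
    assignment (A/B/D) by diagnostic motifs and by nearest labeled reference
    under global-alignment identity, and aggregation of two-dimensional gel
    electrophoresis spot-volume tables into composition summaries. Includes
    seeded generators of gliadin-like sequences and spot tables with exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
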