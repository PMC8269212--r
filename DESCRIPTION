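Package: ramansort
Title: Single-Cell Raman Phenotyping, Sorting Decisions and Single-Cell
    Genome QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for heavy-water (D2O) stable-isotope-probing Raman
    microspectroscopy of single microbial cells and the downstream quality
    control of single-cell amplified genomes. Implements single-cell Raman
    spectrum preprocessing (dark-signal subtraction, asymmetric-least-squares
    baseline correction, C-H band-area normalization), the C-D ratio (CDR)
    statistic used to flag metabolically active cells, carotenoid
    resonance-band detection, joint phenotype classification and sorting
    decision rules, plus sequencing-outcome statistics for sorted cells
    (mapping-rate and completeness aggregation, success rates,
    aligned-base genome completeness, sliding-window GC profiles, canonical
    tetranucleotide contig signatures with 2-D embedding, top-bin taxonomy
    and carotenoid-pathway step coverage). A synthetic-data module generates
    spectra, mock communities, contig sets and sorting outcome tables with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    Rtsne,
    cluster,
    signal,
    e1071,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
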