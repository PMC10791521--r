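Package: recsel
Title: Recombination Rate Dynamics and Genomic Signatures of Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare recombination landscapes between sister species
    and to relate recombination rate and its evolutionary dynamics to genomic
    signatures of indirect and direct selection. Implements interval-weighted
    aggregation of LD-based population-scaled recombination rates into windows
    and genes with conversion to cM/Mb via a pedigree linkage map, a principal
    component based classification of windows into conserved and divergent
    recombination rate, a composite likelihood ratio selective sweep scan
    against a genome-wide background site frequency spectrum, windowed
    Weir-Cockerham FST with per-chromosome Z-transformation, Savitzky-Golay
    smoothing and differentiation-peak calling and classification,
    GC-conservative piN/piS and dN/dS from site-degeneracy classes, Poisson
    random field fits of a gamma distribution of fitness effects with
    demographic nuisance parameters, adaptive substitution rates (omega_a),
    GC-biased gene conversion strength from WS/SW spectra, and permutation
    based comparisons across differentiation-peak categories. Includes a
    seeded synthetic-data generator that emulates the joint structure of
    recombination, diversity, differentiation and coding variation for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    pracma,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
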