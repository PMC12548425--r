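Package: evescreen
Title: Detection, Scoring and Evolutionary Analysis of Endogenous Viral Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering endogenous viral elements
    (EVEs) derived from large double-stranded DNA viruses in host genome
    assemblies. Computes descriptive viral genome features (GC content, open
    reading frames, coding density, tandem direct repeats, inverted repeats),
    performs a translated-homology screen of viral proteins against host
    scaffolds with e-value and query-coverage filtering and short-gap hit
    merging, classifies candidate loci with an additive six-feature confidence
    scoring scheme (premature stop codons, sequencing depth, co-annotated
    eukaryotic genes and transposable elements, GC similarity, scaffold
    length), estimates selection pressure with a Nei-Gojobori (1986) dN/dS
    implementation, and summarises phylogenetic (patristic distance) and
    gene-synteny structure. Includes a ground-truthed synthetic data generator
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
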