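Package: plastome
Title: Comparative Analysis of Chloroplast Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analysis of annotated circular
    chloroplast genomes (plastomes): detection of the inverted-repeat pair
    and partition of the genome into the canonical LSC-IRa-SSC-IRb
    quadripartite layout, calling of the small single-copy (SSC) orientation
    isomer against a reference genome, scanning for perfect microsatellites
    (SSRs) and long direct or inverted repeats, pairwise genome alignment
    with sliding-window nucleotide diversity and six-type substitution
    spectra, gene-level conservation ranking, and neighbor-joining distance
    phylogenies. A synthetic-plastome generator with full ground-truth
    records lets every stage run at desk scale without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
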