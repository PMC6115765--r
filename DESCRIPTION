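Package: tersearch
Title: Synteny-Guided Homology Search for Telomerase RNA in Yeast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for locating the telomerase RNA (TER) gene in budding-yeast
    genomes, where rapid sequence divergence defeats plain homology search.
    Candidate loci are delimited by orthologous flanking protein-coding genes
    (synteny), telomeric repeat units are inferred from chromosome ends and
    used to localize the template region, and a seed-and-extend local aligner
    with Karlin-Altschul E-values, empirical false-positive-rate calibration
    by alignment length, and a homology graph supports clade-wide surveys.
    Conserved TER elements (Sm site, Ku and Est1 hairpins, three-way junction)
    are annotated by motif and hairpin heuristics, and TER boundaries are
    refined iteratively by free-end-gap alignment against the closest known
    TER. A synthetic-clade simulator with planted TER loci provides ground
    truth for recovery benchmarking, and a transcribed survey table of known
    Saccharomycetaceae TER annotations ships as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
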