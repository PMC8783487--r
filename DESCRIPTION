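Package: taxgenomics
Title: Genome-Based Bacterial Taxonomy: ANI, Digital DDH, Pan-Genome
    Orthology and Plant-Growth-Promoting Trait Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating bacterial species from draft genome
    assemblies, built around the workflow used to describe novel Nocardia
    species from actinorhizal root nodules. Computes fragment-based average
    nucleotide identity (OrthoANI-style reciprocal 1020-bp fragment pairing),
    a digital DNA-DNA hybridization distance from high-scoring segment pairs
    with a pluggable distance-to-DDH mapping, pairwise 16S rRNA similarity
    with nucleotide-difference counting, neighbor-joining distance trees,
    reciprocal-best-hit pairwise orthologous groups (POGs) with core /
    accessory / strain-specific partitioning and COG category profiling,
    genome feature tables with a CDS-count-versus-genome-size regression, and
    a curated plant-growth-promoting gene screen. A synthetic genome
    evolution module generates assemblies, pan-genomes and marker pairs with
    known ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
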