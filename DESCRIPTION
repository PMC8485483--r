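Package: paleostrain
Title: Strain-Level Phylogenomics of Ancient Oral Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs reference-anchored draft genomes from damaged
    ancient-DNA read alignments under explicit read- and site-level filters,
    assembles and cleans whole-genome multiple sequence alignments, builds
    recombination-masked neighbor-joining phylogenies with bootstrap support,
    delimits species by average nucleotide identity, and derives core and
    species-specific gene sets from gene presence/absence. Ships a synthetic
    ancient-metagenome generator (clonal strain divergence, kb-scale
    homologous recombination imports, log-normal fragment lengths, terminal
    cytosine deamination damage) with full ground truth, so every stage can
    be validated by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
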