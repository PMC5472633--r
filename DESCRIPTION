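Package: phylodelim
Title: Phylogenomic Species Delineation for Closely Related Bacterial Genera
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for delineating species within a bacterial
    genus from whole-genome data: orthologous-group inference (reciprocal
    best hits plus Markov clustering), single-copy core extraction,
    recombination screening with the PHI, MaxChi and NSS permutation tests,
    distance-based partitioned phylogenies with bootstrap and congruence
    scoring, fragment-based ANI and gene-based gANI/AF species delineation,
    pan-genome rarefaction with Chao1 and ACE richness estimation, and
    16S-marker and trait-based clustering. Ships a synthetic-genus simulator
    with ground-truth species labels, gene families and recombination events
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
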