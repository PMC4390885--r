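Package: dollotrace
Title: Dollo Parsimony Reconstruction of Gene Family Paralog Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs the evolutionary history of gene family copy
    numbers (paralog counts) on a rooted, possibly multifurcating species
    phylogeny under the Dollo assumption that a family arises exactly once.
    Families are dated by the last common ancestor of the species carrying
    them; ancestral paralog counts are inferred with a Sankoff-style
    dynamic program constrained so that no ancestor inside the family's
    subtree can be copy-free; loss branches are read off the reconstruction
    and aggregated into per-branch gain/loss censuses across whole family
    sets. Includes the curation filters used to turn raw homology-search
    hits into accepted microRNA family members, and a simulator of
    duplication/loss histories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
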