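Package: ecoassembly
Title: Ecological Process Inference for Microbial Metacommunities
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the relative contribution of ecological processes
    (heterogeneous and homogeneous selection, dispersal limitation,
    homogenizing dispersal, and drift) to microbial community assembly from
    an OTU table, a rooted phylogeny, and sample metadata. Implements
    abundance-weighted beta-mean nearest taxon distance (betaMNTD) with a
    tip-shuffling null model (betaNTI), the Raup-Crick metric on Bray-Curtis
    dissimilarity (RC-Bray), the Sloan neutral community model, Levins'
    niche breadth, Mantel-family tests, PCNM spatial predictors, and
    variation partitioning, together with a synthetic metacommunity
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
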