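Package: phyllonet
Title: Assembly Processes and Co-Occurrence Networks of Host-Associated
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing host-associated microbial (e.g. nifH
    amplicon) metacommunities across fragmented habitats: alpha and beta
    diversity (Hill numbers, Chao1, Faith phylogenetic diversity,
    Bray-Curtis, weighted UniFrac, PCoA, PERMANOVA, PERMDISP), indicator
    species analysis (IndVal), null-model inference of community assembly
    processes (beta-NTI and Raup-Crick Bray-Curtis with a five-way
    process classification), Spearman co-occurrence networks with module
    detection, Zi-Pi node roles and cohesion, and attack-tolerance
    (robustness) simulation under node and edge removal. Includes a
    seeded synthetic metacommunity generator emulating two-host,
    multi-habitat amplicon surveys so the whole pipeline is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
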