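Package: plasmidcoop
Title: Plasmid-Mediated Cooperation Under Horizontal Gene Transfer
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic models of public-goods cooperation encoded on
    conjugative plasmids in patch-structured bacterial populations. Provides
    deterministic haploid genotype-frequency recursions for a lifecycle with
    N founders per patch, clonal growth, pairwise horizontal gene transfer
    blocked by plasmid incompatibility, shared public-good benefits,
    segregation loss and global dispersal; an exact enumeration calculator
    for whole-group relatedness at plasmid and chromosomal loci; equilibrium,
    invasion and parameter-sweep analyses of when plasmids evolve to be
    cooperative and how common they become; and a stochastic individual-based
    simulator of the identical lifecycle used to validate the deterministic
    recursions and the relatedness expression.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
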