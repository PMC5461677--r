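Package: psyllidwebs
Title: Molecular Food-Web Inference for Psyllid-Parasitoid Communities
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct host-parasitoid food webs of
    Eucalyptus-feeding psyllids from molecular data. Computes pairwise
    p-distance divergence matrices from aligned sequences, delimits putative
    cryptic species by divergence-threshold clustering, designs
    morphospecies-specific multiplex PCR primer panels and validates them by
    in-silico PCR, infers trophic roles (primary parasitoid, hyperparasitoid,
    heteronomous hyperparasitoid) forensically from DNA-detection patterns in
    post-emergence mummies, and tests cophylogenetic congruence between host
    and parasitoid phylogenies with permutation-based ParaFit and Hommola
    cospeciation tests plus exhaustive event-based reconciliation for small
    trees. A synthetic-data generator (Yule trees, Jukes-Cantor sequence
    evolution, codivergence/host-switch simulation, mummy-table simulation)
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    yaml,
    digest,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    phangorn
Config/testthat/edition: 3
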