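Package: provnet
Title: Multi-Layer Social Network Analysis of a Food-Provisioning Perturbation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how a controlled, individual-level
    perturbation (one "provider" female given control of a high-quality
    food resource) changes social network position in a primate group.
    Builds weighted behavioural networks (aggression, displacement,
    peaceful silent bared-teeth displays, grooming, huddling, proximity)
    from dyadic event logs for a baseline and an experimental phase,
    computes degree and strength centrality, focal-change z-statistics
    against the group change distribution, grooming balance, dominance
    ranks from a win-loss matrix completed with transitive network
    pathways, and kin/rank composition of the focal's partners. Includes
    a synthetic-data generator that emulates the study design, with
    injectable multiplicative effects on the focal's dyadic rates, and a
    config-driven pipeline that reproduces the study's summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
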