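Package: fragpick
Title: Protein Fragment Databases and Triangle-Inequality Structural Queries
Version: 0.1.0
Authors@R: person("fragpick", "developers", role = c("aut", "cre"),
    email = "fragpick@example.org")
Description: Builds queryable backbone-fragment databases from sets of PDB
    files and answers structural queries (a query fragment plus an RMSD
    threshold) in sub-linear time.  Superposition RMSD is a metric, so
    precomputed distances to a small set of reference fragments prune the
    search space through the triangle inequality before exact refinement.
    Includes a QCP (quaternion characteristic polynomial) RMSD kernel with an
    independent Kabsch oracle, a compact binary database format, sequence
    regular-expression constraints, gapped (masked) queries, a one-versus-many
    backbone RMSD ranker, deterministic synthetic-structure generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
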