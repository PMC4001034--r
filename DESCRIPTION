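Package: csagen
Title: Connection-Set Algebra and a Generic Connection-Generator Interface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declarative specification of neuronal-network connectivity using the
    connection-set algebra (CSA): lazy, possibly-infinite masks (one-to-one,
    Bernoulli random, Cartesian products, explicit lists) combined with set
    operators, plus value sets that attach per-connection parameters such as
    weights and distance-dependent delays.  Connection-sets are consumed through
    a generic connection-generator iteration protocol that supports per-rank
    mask partitioning for parallel simulators, an XML serialization dialect
    with a pluggable parser registry, a mock simulator kernel mapping global
    identifiers (GIDs) to algebra indices, and command-line tools that
    materialize edge lists and run connection-count scaling benchmarks.
    Random masks use a counter-based hash so that membership of every pair is
    a pure function of (seed, source, target), making realizations identical
    across ranks, iteration orders and machines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
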