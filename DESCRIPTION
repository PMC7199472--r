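Package: cmr
Title: Container-Backed MapReduce Primitives for Bioinformatics Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-machine MapReduce engine whose per-partition
    transformations are carried out by shell commands running in application
    containers (or a no-isolation subprocess sandbox). Plain-text and
    binary-file datasets are split into partitions with configurable record
    terminators, handed to container commands through file-based mount
    points, and composed into pipelines with three primitives: a
    partition-wise map, a tree-shaped reduce of configurable depth for
    associative-commutative aggregation commands, and key-based
    repartitioning with a deterministic hash partitioner. Includes a
    declarative YAML pipeline runner, a command-line interface, and seeded
    synthetic-data generators (DNA text, SDF-dialect molecule libraries,
    tagged sequencing reads) with native oracles for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
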