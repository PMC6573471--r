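Package: pirnatrap
Title: Individual-Based Simulation of Transposable Element Invasions
    Under the piRNA Cluster Trap Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-time, individual-based Wright-Fisher simulations of
    transposable element (TE) invasions in diploid populations where TE
    proliferation is stopped by insertions into piRNA clusters (the trap
    model).  Provides configurable genome architectures (chromosomes,
    recombination map, piRNA clusters, neutral reference regions), three
    fitness models (linear, exponential, cluster-neutral), closed-form
    establishment and silencing expectations, annotation of the rapid
    invasion / shotgun / inactive phases of an invasion, classification of
    invasion outcomes including the transposition-selection-cluster (TSC)
    balance, and a command-line interface for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
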