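Package: netintegrate
Title: Imbalance-Aware Integration of Protein Networks and Hopfield-Based
    Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Function-specific integration of multiple weighted protein
    networks for automated protein function prediction under strong label
    imbalance. Each input network is projected onto the plane by summing, for
    every protein, the weights towards its positive and negative neighbours
    for one Gene Ontology term; the F-measure of the best linear separator of
    the projected points quantifies the network's informativeness for the
    term and weights its contribution to a consensus network. A cost-sensitive
    Hopfield network run on the consensus ranks and classifies unannotated
    proteins via equilibrium neuron energies normalised to [-1, 1]. Includes
    readers and writers for tab-delimited triplet network files, ego-network
    exploration and JSON/CSV subgraph export, seeded generators of planted
    benchmark network collections, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
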