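Package: salesmap
Title: Genetic Linkage Map Construction with Traveling-Salesperson Solvers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds genetic linkage maps from dense marker data by posing
    marker ordering as a Hamiltonian path problem. Pairwise recombination
    frequencies are estimated from genotype matrices (recombinant inbred
    lines, backcrosses, F2 intercrosses), linkage groups are identified by
    minimum-spanning-tree decomposition with TSP-path-guided splitting and a
    three-stage merge, and markers within each group are ordered by a
    dynamic-programming exact solver for small groups or a chained 2-opt/Or-opt
    local search for large ones. Includes a mapping-population simulator with
    configurable genotyping-error and missing-data rates, and solution-quality
    metrics (erroneous marker pairs, linkage-group counts, rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
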