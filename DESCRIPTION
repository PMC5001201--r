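Package: epitracer
Title: Epicenter Detection in Condition-Specific Biological Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies epicenters -- nodes from which highly active paths
    ripple out in one experimental condition -- in a directed molecular
    interaction network overlaid with per-condition gene expression.
    Expression intensities become node weights, edge costs are the inverse
    square root of the product of endpoint weights, and all-pairs
    lowest-cost (highest-activity) paths are extracted per condition with a
    percentile cutoff. Paths common to both conditions are discarded, the
    remaining paths induce condition-specific highest activity networks,
    and nodes are ranked by ripple centrality: the product of normalized
    outward closeness and normalized outward reachability. Includes
    influence-zone summaries of dysregulated genes around an epicenter,
    rank-stability (sensitivity) analysis under bounded multiplicative
    noise, and a synthetic planted-epicenter generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
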