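Package: trendtree
Title: Temporal Trends in Phenotypic Means and Evolutionary Rates on
    Phylogenies with Fossils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects temporal trends in the magnitude of phenotypic
    evolutionary rates and directional drift in the phenotypic mean along
    rooted, possibly non-ultrametric phylogenies that include extinct
    lineages. Per-branch rates and ancestral states are estimated by
    normalized phylogenetic ridge regression anchored on a root value
    computed from the most ancient tips. Trend and drift regression slopes
    are compared by rank against families of slopes obtained from Brownian
    motion simulations on the same tree, and individual clades can be
    contrasted against the tree background or against each other via
    age-adjusted (estimated marginal mean) rate comparisons and
    clade-restricted drift slopes. Includes the full simulation machinery
    used to validate the method: birth-death tree generation with fossils,
    Brownian trait simulation, rate-trend and mean-drift phenotype
    transforms, deviation metrics, and power / Type-I-error batteries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    stats,
    utils
Suggests:
    emmeans,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
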