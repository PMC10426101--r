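Package: phylodag
Title: Exploratory Phylogenetic Path Analysis over Exhaustive Causal Model Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploratory phylogenetic path analysis of comparative
    trait data. Enumerates every directed acyclic causal model over a set of
    species or society traits under user-declared exogeneity constraints,
    scores each model by phylogenetic d-separation (Fisher's C and the
    small-sample C-statistic information criterion, CICc), and returns a
    conditionally averaged best causal model with confidence intervals.
    Includes phylogenetic generalised least squares with a profiled
    correlation parameter (Pagel's lambda or an Ornstein-Uhlenbeck alpha),
    the Fritz-Purvis D statistic for binary-trait phylogenetic signal,
    permutation tests of association between distance matrices, construction
    of trees from nested taxonomic or linguistic classifications, and a
    synthetic-data generator with a known generating causal structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    nlme,
    vegan,
    geosphere,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
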