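Package: clamap
Title: Consensus Linkage Maps from Multiple Biparental Populations and
    Inclusive Composite Interval Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds consensus genetic linkage maps from several recombinant
    inbred line (RIL) or doubled haploid (DH) populations by combined
    linkage analysis: per-population two-point recombination-frequency
    estimation with sampling variances, inverse-variance combination across
    populations, and marker ordering by a nearest-neighbour plus 2-opt
    travelling-salesman heuristic. Includes an inclusive composite interval
    mapping (ICIM) scanner for additive QTL with stepwise cofactor
    selection and an EM mixture fit, a seeded RIL/DH population simulator
    with additive QTL models and heritability-scaled noise, and a
    simulation harness that estimates QTL detection power, false discovery
    rate and confidence-interval length on individual versus consensus
    maps. Marker quality control, map summary statistics and map
    collinearity diagnostics are provided as tidy verbs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
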