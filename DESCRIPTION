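Package: breedopt
Title: State-Dependent Optimization of Breeding Phenology in Capital and
    Income Breeding Birds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dynamic state variable model of nesting phenology for migratory
    birds that finance reproduction from stored reserves (capital breeders)
    or from concurrent food intake (income breeders). Computes the optimal
    forage/lay/incubate policy on a reserves x day x clutch lattice by
    backward induction under a discretized beta distribution of daily net
    food gain, simulates cohorts of females following that policy under
    stochastic daily gains, and sweeps spring-onset date against food-gain
    variance to compare nesting onset, clutch size and offspring recruitment
    between the two strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
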