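Package: arrivaldyn
Title: Eco-Evolutionary Dynamics of Arrival Timing in Migratory Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the evolution of mean arrival date at the breeding
    grounds for long-distance migratory birds facing a seasonal trade-off
    between pre-breeding survival (which improves with later arrival) and
    reproduction (which declines with later arrival), with density-dependent
    territory competition under prior residency. Provides the within-year
    arrival/competition process, the between-year population map and its
    equilibrium, invasion fitness and selection gradients for variant
    arrival strategies, evolutionarily stable strategy (ESS) computation
    with full eco-evolutionary feedback, and climate-change experiments
    that shift the onset of spring and the food-peak date and report the
    resulting selection gradients, density ratios and age-structure
    responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
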