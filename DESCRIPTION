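Package: firecarbon
Title: Long-Term Forest Carbon Balance Reconstruction with Wildfire,
    Harvest and Grazing Removals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs continuous national and regional burned-forest-area
    series from overlapping, partially discontinued reporting sources
    (historical agency statistics spliced with satellite land-cover summaries),
    converts burned area to biomass carbon using compartment-resolved fuel
    loads and combustion-completeness fractions, assembles decadal forest
    carbon balances whose net-ecosystem-productivity proxy equals biomass
    stock change plus removals by fire, wood harvest and forest grazing, and
    quantifies uncertainty with a factorial min/max sensitivity design. A
    seeded synthetic-world generator renders multi-source input files with
    known ground truth so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    yaml,
    generics,
    stats,
    utils,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
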