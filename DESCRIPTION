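Package: larvconnect
Title: Larval Dispersal Connectivity on Synthetic Coastal Ocean Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale biophysical modelling of mussel larval dispersal and
    connectivity. Generates synthetic coastal domains (bathymetry, land mask,
    fjords, a counterclockwise gyre with a coastal jet, seasonal temperature),
    schedules parameterized larval releases with exact window and depth-band
    quotas, advects passive particles forward or backward in time with a
    minimal Lagrangian tracker, scores settlement as the fraction of the
    competency window spent over shallow habitat on a regular grid, assembles
    site-to-site connectivity matrices with retention and source/sink degree
    summaries, interpolates connectivity surfaces by ordinary kriging, and
    compares inner versus outer archipelago sites with quasi-likelihood
    generalized linear models. A companion population-genomics component
    simulates multi-lineage genotype datasets and applies coverage, identity by
    state relatedness, locus, and admixture-coefficient filtering rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
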