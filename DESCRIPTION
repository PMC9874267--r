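Package: ageresist
Title: Evolution of Age-Specific Resistance to Infectious Disease
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how innate, infection-preventing resistance
    evolves at juvenile and adult life stages when resistance trades off with
    other life-history traits (maturation, reproduction or mortality). Provides
    the age-structured susceptible-infected ecological model (ordinary
    differential equations, disease-free and endemic equilibria, basic
    reproduction number), evolutionary invasion analysis (invasion fitness,
    selection gradients, co-singular strategies with evolutionary and strong
    convergence stability, phase planes with nullclines and basins of
    attraction), stochastic trait-substitution simulations, and parameter-sweep
    drivers with bistability detection. Tidyverse-native: functions take and
    return data frames, results have tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
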