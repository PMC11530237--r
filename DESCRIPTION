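Package: agebd
Title: Evolution of Ageing in a Two-Gene Birth-Death Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic and deterministic tools for a minimal life-history
    model of ageing in which each haploid, asexual individual carries two
    heritable traits: the end of its fertility span (x_b) and the onset of
    its intrinsic mortality risk (x_d). The package provides an exact
    individual-based birth-death-mutation simulator under logistic
    competition (with an optional Lansing transgenerational effect),
    Euler-Lotka Malthusian-fitness solvers and selection-gradient
    landscapes for Lansing and non-Lansing genotypes, canonical-equation
    trait dynamics with the closed-form asymptotic fertility-mortality
    gap, and scripted competition experiments between Lansing and
    non-Lansing populations with tidy summaries and ggplot2 methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
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
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
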