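Package: antborer
Title: Predator-Prey Dynamics of Coffee Berry Borer Biocontrol by Predatory Ants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the qualitative and numerical analysis of a
    stage-structured predator-prey model of the coffee berry borer
    (Hypothenemus hampei; adult and immature stages) under predation by
    ants. Computes net reproductive rate thresholds, the four closed-form
    equilibria and their stability via Jacobian eigenvalues, transcritical
    bifurcation certificates (Sotomayor conditions), verification of the
    positively invariant region, numerical trajectories, and integrated
    pest-management scenario sweeps relating ant predation rates to the
    additional adult mortality needed to eradicate the pest.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
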