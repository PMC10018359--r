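Package: sedstoich
Title: Sedimentation and Light-Scattering Analysis of Protein-ssDNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for macromolecular interaction studies by
    analytical ultracentrifugation and static light scattering. Provides a
    conservative finite-volume Lamm equation solver for sedimentation-velocity
    forward modelling, regularized non-negative inversion into c(s)
    sedimentation-coefficient distributions, global nonlinear least-squares
    fitting of sedimentation-equilibrium profiles with mass-conservation
    constraints, partial-specific-volume and buoyancy bookkeeping, complex
    stoichiometry enumeration against fitted molar masses, and normalization
    plus aggregation-onset (changepoint) detection for light-scattering
    titrations. A seeded synthetic-data generator produces equilibrium
    profiles, velocity scan sets and titration series so every stage is
    testable without instrument data.
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
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
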