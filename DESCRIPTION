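Package: thinfilament
Title: Multiscale Modeling of Tropomyosin Mechanics and Cardiac Thin-Filament
    Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links residue-level tropomyosin properties to sarcomere-level
    function. Converts per-residue flexibility profiles of the tropomyosin
    coiled coil into an effective chain stiffness through a torsional-spring
    cable model, maps blocked-to-closed interaction-energy changes onto the
    blocked-closed equilibrium constant through the Gibbs relation, and feeds
    both into a stochastic 24-state Markov model of 26 thin-filament
    regulatory units in series. Provides steady-state force-pCa and isometric
    twitch protocols, Hill-equation calcium-sensitivity fitting, twitch
    metrics, and a synthetic generator for the upstream molecular-dynamics
    style inputs, supporting wild-type versus mutant comparisons such as
    TPM1 S215L.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
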