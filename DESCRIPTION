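Package: chargedrods
Title: Equation of State of Charged Rodlike Colloids via Effective
    Diameters, Scaled Particle Theory and Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Thermodynamics of isotropic suspensions of charged hard
    spherocylinders (viruses, DNA fragments, cellulose nanocrystals).
    Implements the Debye-Hueckel amplitude of the screened rod-rod
    repulsion (exact Bessel-function form, thick- and thin-double-layer
    asymptotes, and a uniform approximation), the
    Stroobants-Lekkerkerker-Odijk (SLO) effective diameter (closed form
    and the exact orientation-averaged integral for finite or infinite
    interaction cutoff, including the threshold-cutoff analysis), scaled
    particle theory equations of state for hard and charged rods with the
    free-volume route to the osmotic pressure, Metropolis Monte Carlo of
    spherocylinders interacting through a truncated-shifted screened
    Coulomb potential, Widom test-particle insertion estimators of the
    free volume fraction, and drivers that compare theory against
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
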