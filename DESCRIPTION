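Package: membind
Title: Peptide-Membrane Binding Isotherms and Bilayer Surface Electrostatics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Equilibrium analysis of cationic peptide binding to anionic
    lipid bilayers. Provides Langmuir single-site binding isotherm models
    and fits for both peptide-into-lipid and lipid-into-peptide titrations,
    Scatchard transforms and molar partition coefficients, Gouy-Chapman-Stern
    diffuse double-layer electrostatics with Stern charge regulation and
    zeta-potential conversions, a one-site isothermal titration calorimetry
    forward model with Wiseman-plot fitting and thermodynamic decomposition,
    fluorescence-derived membrane statistics (generalized polarization,
    steady-state anisotropy, Stern-Volmer quenching), a coupled-equilibrium
    model of divalent cation accumulation at charged membrane interfaces,
    and seeded synthetic-data generators for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
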