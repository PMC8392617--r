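Package: actmech
Title: Gas-Phase Thermochemistry and Reaction Kinetics from Molecular
    Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes absolute entropies, entropic energies, enthalpies and
    Helmholtz/Gibbs energies of ideal-gas species directly from tabulated
    molecular constants (masses, bond lengths, moments of inertia,
    vibrational wavenumbers, symmetry and electronic degeneracy) using the
    action-mechanics partitioning of entropy into translational, rotational
    and vibrational quantum numbers.  From the species state functions it
    assembles reaction thermodynamics (bond-enthalpy reaction enthalpies
    with Kirchhoff temperature correction, T*dS, dG(T), equilibrium
    constants, temperature scans and dG = 0 crossings) and action-revised
    transition-state quantities (Boltzmann activated fractions, kT/h rate
    constants, forward/reverse ratios and radial-excitation tables).
    Includes a small plain-text species/bond registry format and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
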