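Package: quadlink
Title: Linked-Equilibrium Thermodynamics of G-Quadruplex Folding and Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic analysis of G-quadruplex folding intermediates and
    small-molecule ligand binding under potassium-ion linkage.  Implements a
    seven-species linked-equilibrium model (unfolded strand, two-quartet
    intermediate, folded quadruplex, and their 1:1 and 2:1 ligand complexes),
    Gibbs-Helmholtz propagation of standard-state parameters across temperature
    and salt, mass-action speciation with free-ligand root finding, forward
    models for circular dichroism melting curves, differential scanning
    calorimetry thermograms and isothermal titration calorimetry isotherms,
    singular-value-decomposition rank analysis of temperature-series spectra,
    weighted multi-experiment global fitting with multi-start bounded least
    squares, binding free-energy decomposition, and construction of
    stability pseudophase diagrams with refined boundaries and triple points.
    Includes a seeded synthetic-data generator emulating the three experiment
    types for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
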