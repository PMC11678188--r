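Package: CoexTherm
Title: Thermodynamics of Gel-Fluid Phase Coexistence in Lipid Membranes
    from DSC and Spin-Label ESR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the thermodynamic analysis of gel-fluid phase
    coexistence in lipid model membranes such as pulmonary-surfactant
    mimics. Processes differential scanning calorimetry (DSC) thermograms
    into melting temperature, calorimetric and van't Hoff enthalpies,
    transition entropy and cooperative unit size; decomposes two-component
    nitroxide spin-label ESR spectra into ordered/disordered lipid
    populations; and fits a non-linear (polynomial in 1/T) van't Hoff
    model to the population equilibrium constant, yielding
    temperature-dependent Gibbs energy, enthalpy, entropy and heat
    capacity changes with special temperatures, entropy-enthalpy
    compensation analysis and bootstrap confidence bands. A synthetic-data
    generator produces thermograms and two-component nitroxide spectra
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'CoexTherm-package.R'
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'dsc.R'
    'esr.R'
    'vanthoff.R'
    'io.R'
    'pipeline.R'
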