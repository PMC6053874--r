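Package: dhbpka
Title: Spectrophotometric and Thermodynamic-Cycle pKa Determination for
    Substituted Catechols
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for determining acid dissociation constants (pKa) of
    substituted 1,2-dihydroxybenzenes (catechols) from UV-Vis pH-titration
    spectra and from quantum-chemical free energies.  Implements polyprotic
    equilibrium speciation, a synthetic titration-spectra generator, five
    spectrophotometric estimation methods (isosbestic-point intersection on
    raw and Savitzky-Golay derivative spectra, the zero-crossing method, the
    baseline-to-peak log-ratio fit, and the three-point Seok closed form)
    organised in a method-selection cascade, a thermodynamic-cycle pKa
    calculator with the Pliego proton-exchange correction, and validation
    analyses: solvation-model relative errors, experimental-versus-computed
    correlation, and Hammett sigma based assignment of the first
    deprotonation site.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
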