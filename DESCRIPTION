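Package: redoxpH
Title: pH-Dependent One-Electron Oxidation Potentials from Quantum-Chemical Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts species-level solution-phase free energies and acidity
    constants into pH-dependent one-electron oxidation potentials for
    nucleobase derivatives. Implements a hierarchy of four potential models
    (raw thermodynamic-cycle potential, Henderson-Hasselbalch mole-fraction
    averaging over the neutral and deprotonated oxidation pathways, and two
    Nernst prototropic-equilibrium corrections), Boltzmann-weighted
    conformer/tautomer ensemble free energies with deduplication and
    contribution filtering, two-point complete-basis-set extrapolation,
    theory-versus-experiment linear calibration with censored-value handling,
    and a slope-and-anchor linear adjustment of computed potentials. Ships
    transcriptions of the benchmark tables and a synthetic-system generator
    with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
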