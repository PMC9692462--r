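Package: radaudit
Title: Consistency Audits for Free-Radical-Scavenging Thermochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the five thermochemical descriptors of the HAT,
    SET-PT and SPLET free-radical-scavenging mechanisms (BDE, IP, PDE,
    PA, ETE) from species enthalpies, evaluates the medium-dependent
    ionization enthalpy of the hydrogen atom from a built-in catalog of
    reference-particle enthalpies and solvation corrections, and audits
    reported descriptor tables against two exact Hess's-law identities
    (the equality of the combined SET-PT and SPLET pathway enthalpies,
    and their fixed offset from BDE).  Violations are flagged with
    rounding-aware tolerances and diagnosed (unit mix-ups, gas/solvent
    mislabeling, gross inconsistency).  Includes a generic exact
    stoichiometric identity-discovery engine and a seeded synthetic
    fixture generator with controlled fault injection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
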